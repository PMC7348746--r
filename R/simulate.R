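#' Generate a toy genome annotation
#'
#' Lays out non-overlapping gene bodies along `n_chroms` chromosomes with
#' intergenic spacing drawn from `spacing_range`, alternating random
#' strands (both strands always represented). Each gene gets 1-4 exons
#' spanning its body and, for a `coding_fraction` of genes, a CDS occupying
#' the central half of the body; the rest are non-coding.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_chroms Number of chromosomes.
#' @param gene_length_range,spacing_range Ranges (bp) for gene body lengths
#'   and intergenic gaps. The default minimum spacing of 12 kb keeps every
#'   TSS more than 5 kb from neighbouring gene bodies, so TSS-window
#'   assignments are unambiguous.
#' @param coding_fraction Fraction of genes given a CDS (default 0.8).
#' @param chrom_length Optional fixed chromosome length; an error is thrown
#'   if the genes do not fit.
#' @param seed Integer seed; the same seed reproduces the same annotation.
#' @return A [genome_annotation()].
#' @export
generate_annotation <- function(n_genes = 500, n_chroms = 2,
                                gene_length_range = c(2000, 10000),
                                spacing_range = c(12000, 20000),
                                coding_fraction = 0.8,
                                chrom_length = NULL, seed = 1) {
  stopifnot(n_genes >= 1, n_chroms >= 1)
  with_stream(seed, "annotation", {
    per_chrom <- rep(n_genes %/% n_chroms, n_chroms)
    extra <- n_genes %% n_chroms
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1
    id_width <- max(3, nchar(n_genes))
    rows <- list()
    sizes <- numeric(n_chroms)
    names(sizes) <- paste0("chr", seq_len(n_chroms))
    gid <- 0
    for (ci in seq_len(n_chroms)) {
      pos <- 10000
      for (k in seq_len(per_chrom[ci])) {
        gid <- gid + 1
        len <- round(stats::runif(1, gene_length_range[1],
                                  gene_length_range[2]))
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample(1:4, 1)
        if (n_ex > 1) {
          grid <- seq(100, len - 100, by = 50)
          brk <- sort(sample(grid, 2 * (n_ex - 1)))
        } else {
          brk <- numeric(0)
        }
        edges <- c(0, brk, len)
        starts <- pos + edges[seq(1, length(edges) - 1, by = 2)]
        ends <- pos + edges[seq(2, length(edges), by = 2)]
        coding <- stats::runif(1) < coding_fraction
        rows[[gid]] <- tibble::tibble(
          gene_id = sprintf("g%0*d", id_width, gid),
          chrom = names(sizes)[ci],
          start = pos, end = pos + len, strand = strand,
          cds_start = if (coding) pos + round(0.25 * len) else NA_real_,
          cds_end = if (coding) pos + round(0.75 * len) else NA_real_,
          exon_starts = list(starts), exon_ends = list(ends)
        )
        pos <- pos + len +
          round(stats::runif(1, spacing_range[1], spacing_range[2]))
      }
      sizes[ci] <- pos + 10000
      if (!is.null(chrom_length)) {
        if (sizes[ci] > chrom_length) {
          stop("chromosome capacity exceeded: chr", ci, " needs ",
               sizes[ci], " bp but chrom_length is ", chrom_length,
               call. = FALSE)
        }
        sizes[ci] <- chrom_length
      }
    }
    genes <- dplyr::bind_rows(rows)
    # guarantee both strands appear
    if (n_genes >= 2 && length(unique(genes$strand)) == 1) {
      genes$strand[n_genes] <- setdiff(c("+", "-"), genes$strand[1])
    }
    genome_annotation(genes, sizes)
  })
}

default_state_fractions <- function() {
  c("1111" = 0.10,  # stable poised across all conditions
    "1101" = 0.010, # resolved in adult controls, re-poised in adult IUGR
    "0010" = 0.010, # de novo poised only in adult controls
    "0101" = 0.006, # gained in 2-wk IUGR, maintained at 10 wk
    "1010" = 0.006, # lost in 2-wk IUGR, control keeps the poised state
    "0011" = 0.010) # de novo poised at 10 wk in both groups
}

plant_pair <- function(tss, width_range, ov, jitter_sd) {
  w4 <- round(stats::runif(1, width_range[1], width_range[2]))
  w27 <- round(stats::runif(1, width_range[1], width_range[2]))
  ov_start <- tss - floor(ov / 2)
  k4 <- c(ov_start + ov - w4, ov_start + ov)
  k27 <- c(ov_start, ov_start + w27)
  if (jitter_sd > 0) {
    k4 <- k4 + round(stats::rnorm(2, 0, jitter_sd))
    k27 <- k27 + round(stats::rnorm(2, 0, jitter_sd))
  }
  list(k4 = c(max(0, k4[1]), max(max(0, k4[1]) + 1, k4[2])),
       k27 = c(max(0, k27[1]), max(max(0, k27[1]) + 1, k27[2])))
}

#' Generate condition-level peak sets with planted bivalent promoters
#'
#' Genes are assigned a 4-condition bivalency state vector according to
#' `state_fractions` (names are 4-bit codes ordered 2wk control, 2wk IUGR,
#' 10wk control, 10wk IUGR; unassigned genes are never poised). In every
#' condition where a gene is poised it receives an H3K4me3 and an H3K27me3
#' peak overlapping by `min_overlap + overlap_margin` bp centred on its
#' TSS; in conditions where it is not poised, a poised-elsewhere gene keeps
#' only its H3K4me3 peak. A random half of never-poised genes carry
#' H3K4me3 and H3K27Ac promoter peaks (active genes), and background
#' H3K27me3 peaks are placed mid-gap between genes, far from any TSS.
#' Boundary jitter (`jitter_sd` > 0) erodes the planted overlaps so
#' recovery degrades gracefully; `jitter_sd = 0` gives exact geometry.
#'
#' @param annotation A [genome_annotation()].
#' @param state_fractions Named fractions of genes per state code; must sum
#'   to at most 1.
#' @param peak_width_range Peak widths in bp.
#' @param jitter_sd Gaussian SD (bp) added to each peak boundary.
#' @param min_overlap,overlap_margin Planted overlap is
#'   `min_overlap + overlap_margin` bp (defaults 5 + 45).
#' @param seed Integer seed.
#' @return A list: `peaks` (tibble over all marks and conditions) and
#'   `manifest` (tibble with `gene_id`, `state_code`, `active`, and one
#'   logical `planted_<condition>` column per condition).
#' @export
generate_condition_peaks <- function(annotation,
                                     state_fractions =
                                       default_state_fractions(),
                                     peak_width_range = c(500, 1500),
                                     jitter_sd = 0,
                                     min_overlap = 5, overlap_margin = 45,
                                     seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (sum(state_fractions) > 1 + 1e-9) {
    stop("state_fractions must sum to at most 1", call. = FALSE)
  }
  if (length(state_fractions) > 0 &&
      !all(grepl("^[01]{4}$", names(state_fractions)))) {
    stop("state_fractions names must be 4-bit codes", call. = FALSE)
  }
  genes <- annotation$genes
  n <- nrow(genes)
  with_stream(seed, "peaks", {
    ord <- sample.int(n)
    counts <- round(state_fractions * n)
    state <- rep("0000", n)
    at <- 1
    for (k in seq_along(counts)) {
      if (counts[k] == 0) next
      state[ord[at:(at + counts[k] - 1)]] <- names(counts)[k]
      at <- at + counts[k]
    }
    active <- state == "0000" & stats::runif(n) < 0.5
    ov <- min_overlap + overlap_margin
    conds <- design_conditions()
    out <- list()
    planted <- matrix(FALSE, nrow = n, ncol = 4,
                      dimnames = list(NULL, conds))
    row_id <- 0
    add_peak <- function(chrom, start, end, mark, cond) {
      row_id <<- row_id + 1
      parts <- strsplit(cond, "_", fixed = TRUE)[[1]]
      out[[row_id]] <<- tibble::tibble(
        chrom = chrom, start = start, end = end, mark = mark,
        age = parts[1], group = parts[2],
        score = NA_real_, qvalue = NA_real_, qvalue_scale = NA_character_
      )
    }
    for (i in seq_len(n)) {
      bits <- as.integer(strsplit(state[i], "")[[1]]) == 1
      for (ci in seq_along(conds)) {
        if (bits[ci]) {
          pr <- plant_pair(genes$tss[i], peak_width_range, ov, jitter_sd)
          add_peak(genes$chrom[i], pr$k4[1], pr$k4[2], "H3K4me3", conds[ci])
          add_peak(genes$chrom[i], pr$k27[1], pr$k27[2], "H3K27me3",
                   conds[ci])
          planted[i, ci] <- TRUE
        } else if (state[i] != "0000" || active[i]) {
          w <- round(stats::runif(1, peak_width_range[1],
                                  peak_width_range[2]))
          s0 <- max(0, genes$tss[i] - round(w / 2))
          add_peak(genes$chrom[i], s0, s0 + w, "H3K4me3", conds[ci])
          if (active[i]) {
            add_peak(genes$chrom[i], s0, s0 + w, "H3K27Ac", conds[ci])
          }
        }
      }
    }
    # background H3K27me3 mid-gap between consecutive genes (never within
    # the promoter window of a TSS at the default spacing)
    for (cc in unique(genes$chrom)) {
      g <- genes[genes$chrom == cc, ]
      g <- g[order(g$start), ]
      if (nrow(g) < 2) next
      gaps <- which(stats::runif(nrow(g) - 1) < 0.3)
      for (k in gaps) {
        mid <- floor((g$end[k] + g$start[k + 1]) / 2)
        for (cond in conds) {
          add_peak(cc, mid - 500, mid + 500, "H3K27me3", cond)
        }
      }
    }
    manifest <- tibble::tibble(gene_id = genes$gene_id,
                               state_code = state, active = active)
    for (cond in conds) {
      manifest[[paste0("planted_", cond)]] <- planted[, cond]
    }
    list(peaks = dplyr::bind_rows(out), manifest = manifest)
  })
}

default_regulation_fractions <- function() {
  c(all3_up = 0.01,      # all three marks concordant, expression up
    all3_down = 0.01,    # all three marks concordant, expression down
    partial_up = 0.04,   # H3K4me3 + H3K27Ac concordant, no H3K27me3 site
    partial_down = 0.04,
    discordant = 0.02)   # H3K27me3 moves with expression (wrong way)
}

#' Generate differential-site and expression tables with planted structure
#'
#' Genes are assigned regulation classes by `class_fractions`; unassigned
#' genes are nulls. A planted concordant gene receives, at both ages,
#' differential sites within `site_max_offset` bp of its TSS whose log2
#' fold-changes follow the concordance rule (activating marks move with the
#' planted expression change, H3K27me3 against it) and FDRs below 0.05,
#' together with a significant expression change of the planted sign.
#' `partial_*` genes lack the H3K27me3 site, `discordant` genes have the
#' H3K27me3 site moving the wrong way, and null genes get either no sites
#' or non-significant ones. `noise_sd` perturbs mark log2 fold-changes so
#' planted signs can flip.
#'
#' @param annotation A [genome_annotation()].
#' @param class_fractions Named fractions over the regulation classes.
#' @param effect_size_range Magnitude range for planted log2 fold-changes.
#' @param noise_sd Gaussian SD added to planted mark log2 fold-changes.
#' @param site_max_offset Maximum planted site-midpoint distance from the
#'   TSS (default 4000 bp, inside the 5 kb assignment window).
#' @param poised_genes Gene ids to treat as poised: expressed at very low
#'   abundance (below 1) in every group.
#' @param seed Integer seed.
#' @return A list: `diff` (differential sites over marks and ages),
#'   `expression` (per-age records with per-group mean abundances) and
#'   `manifest` (gene, class, planted direction).
#' @export
generate_diff_and_expression <- function(annotation,
                                         class_fractions =
                                           default_regulation_fractions(),
                                         effect_size_range = c(0.5, 2),
                                         noise_sd = 0,
                                         site_max_offset = 4000,
                                         poised_genes = character(),
                                         seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (sum(class_fractions) > 1 + 1e-9) {
    stop("class_fractions must sum to at most 1", call. = FALSE)
  }
  stopifnot(all(effect_size_range > 0))
  genes <- annotation$genes
  n <- nrow(genes)
  with_stream(seed, "regulation", {
    ord <- sample.int(n)
    counts <- round(class_fractions * n)
    class <- rep("null", n)
    at <- 1
    for (k in seq_along(counts)) {
      if (counts[k] == 0) next
      class[ord[at:(at + counts[k] - 1)]] <- names(counts)[k]
      at <- at + counts[k]
    }
    mag <- function(k = 1) stats::runif(k, effect_size_range[1],
                                        effect_size_range[2])
    diff_rows <- list()
    expr_rows <- list()
    di <- 0
    add_site <- function(i, mark, age, lfc, fdr) {
      di <<- di + 1
      offset <- round(stats::runif(1, -site_max_offset, site_max_offset))
      w <- round(stats::runif(1, 200, 800))
      s0 <- max(0, genes$tss[i] + offset - round(w / 2))
      diff_rows[[di]] <<- tibble::tibble(
        chrom = genes$chrom[i], start = s0, end = s0 + w,
        mark = mark, age = age,
        log2FC = lfc + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0,
        pvalue = fdr / 2, fdr = fdr
      )
    }
    direction <- ifelse(grepl("down", class), -1,
                        ifelse(class == "null", 0, 1))
    poised <- genes$gene_id %in% poised_genes
    for (age in design_ages()) {
      for (i in seq_len(n)) {
        cl <- class[i]
        s <- direction[i]
        if (cl == "null") {
          rna_fdr <- stats::runif(1, 0.2, 0.9)
          rna_lfc <- stats::rnorm(1, 0, 0.2)
          if (stats::runif(1) < 0.5) {
            add_site(i, sample(histone_marks(), 1), age,
                     stats::rnorm(1, 0, 0.5), stats::runif(1, 0.2, 0.9))
          }
        } else {
          rna_fdr <- stats::runif(1, 1e-4, 0.04)
          rna_lfc <- s * mag()
          add_site(i, "H3K4me3", age, s * mag(), stats::runif(1, 1e-4, 0.04))
          add_site(i, "H3K27Ac", age, s * mag(), stats::runif(1, 1e-4, 0.04))
          if (cl %in% c("all3_up", "all3_down")) {
            add_site(i, "H3K27me3", age, -s * mag(),
                     stats::runif(1, 1e-4, 0.04))
          } else if (cl == "discordant") {
            add_site(i, "H3K27me3", age, s * mag(),
                     stats::runif(1, 1e-4, 0.04))
          }
        }
        ab <- if (poised[i]) stats::runif(2, 0, 0.5) else stats::runif(2, 5, 500)
        expr_rows[[length(expr_rows) + 1]] <- tibble::tibble(
          gene_id = genes$gene_id[i], age = age,
          log2FC = rna_lfc, fdr = rna_fdr,
          mean_abundance_control = ab[1], mean_abundance_IUGR = ab[2]
        )
      }
    }
    manifest <- tibble::tibble(
      gene_id = genes$gene_id, class = class,
      direction = c("none", "up", "down")[match(direction, c(0, 1, -1))],
      poised = poised
    )
    list(diff = dplyr::bind_rows(diff_rows),
         expression = dplyr::bind_rows(expr_rows),
         manifest = manifest)
  })
}

iupac_alphabet <- function() strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Generate motif-enrichment tables with planted persistence classes
#'
#' For each motif and mark, p-values for the four condition tables are
#' drawn so that the planted class is recovered by
#' [classify_motif_change()] at its default thresholds:
#' `persistent_gain` motifs are strongly enriched only in IUGR at both
#' ages (`p <= 1e-6` vs control `p >= 0.1`), `persistent_loss` the mirror,
#' `transient_gain` gains at 2 wk only, `both_enriched` is significant in
#' both groups, and `none` is never enriched.
#'
#' @param motif_spec Tibble with columns `motif_name`, `mark`, `class`
#'   (from the set above); one row per motif x mark.
#' @param seed Integer seed.
#' @return A list: `motifs` (records per motif, mark, age and group) and
#'   `manifest` (`motif_spec` with the generated consensus).
#' @export
generate_motif_tables <- function(motif_spec, seed = 1) {
  classes <- c("persistent_gain", "persistent_loss", "transient_gain",
               "both_enriched", "none")
  if (!all(motif_spec$class %in% classes)) {
    stop("unknown motif class; expected one of: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  with_stream(seed, "motifs", {
    motif_spec$consensus <- vapply(seq_len(nrow(motif_spec)), function(i) {
      paste(sample(iupac_alphabet(), 10, replace = TRUE), collapse = "")
    }, character(1))
    sig <- function() 10^-round(stats::runif(1, 6, 60))
    ns <- function() sample(c(0.1, 1), 1)
    rows <- list()
    k <- 0
    add <- function(i, age, p_iugr, p_control) {
      for (grp in design_groups()) {
        k <<- k + 1
        rows[[k]] <<- tibble::tibble(
          motif_name = motif_spec$motif_name[i],
          consensus = motif_spec$consensus[i],
          mark = motif_spec$mark[i], age = age, group = grp,
          pvalue = if (grp == "IUGR") p_iugr else p_control
        )
      }
    }
    for (i in seq_len(nrow(motif_spec))) {
      cl <- motif_spec$class[i]
      for (age in design_ages()) {
        if (cl == "persistent_gain") add(i, age, sig(), ns())
        if (cl == "persistent_loss") add(i, age, ns(), sig())
        if (cl == "transient_gain") {
          if (age == "2wk") add(i, age, sig(), ns()) else add(i, age, ns(), ns())
        }
        if (cl == "both_enriched") add(i, age, sig(), sig())
        if (cl == "none") add(i, age, ns(), ns())
      }
    }
    list(motifs = dplyr::bind_rows(rows), manifest = motif_spec)
  })
}

#' Write a complete synthetic input bundle
#'
#' Runs the annotation, peak, differential/expression and motif generators
#' at their defaults (or the supplied parameters) and writes every artifact
#' in the plain-text formats the readers consume: a refFlat annotation and
#' chrom sizes, one BED per mark and condition, one differential TSV per
#' mark and age, one expression TSV per age, one motif TSV per mark, age
#' and group, the truth manifests, and a config snapshot.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed driving every generator stream.
#' @param n_genes,n_chroms Passed to [generate_annotation()].
#' @param state_fractions Passed to [generate_condition_peaks()].
#' @param class_fractions Passed to [generate_diff_and_expression()].
#' @param jitter_sd,noise_sd Degradation knobs (0 = noise-free).
#' @param motif_spec Passed to [generate_motif_tables()]; the default
#'   plants 9 persistent H3K4me3 gains, 3 persistent H3K27me3 losses and
#'   assorted neutral motifs.
#' @param force Overwrite an existing bundle.
#' @return Invisibly, a list with the in-memory artifacts and the paths
#'   written.
#' @export
simulate_bundle <- function(out_dir, seed = 1, n_genes = 500, n_chroms = 2,
                            state_fractions = default_state_fractions(),
                            class_fractions =
                              default_regulation_fractions(),
                            jitter_sd = 0, noise_sd = 0,
                            motif_spec = default_motif_spec(),
                            force = FALSE) {
  ann <- generate_annotation(n_genes = n_genes, n_chroms = n_chroms,
                             seed = seed)
  pk <- generate_condition_peaks(ann, state_fractions = state_fractions,
                                 jitter_sd = jitter_sd, seed = seed)
  poised <- pk$manifest$gene_id[pk$manifest$state_code != "0000"]
  de <- generate_diff_and_expression(ann, class_fractions = class_fractions,
                                     noise_sd = noise_sd,
                                     poised_genes = poised, seed = seed)
  mo <- generate_motif_tables(motif_spec, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p) && !force) {
      stop("bundle file exists (use force = TRUE): ", name, call. = FALSE)
    }
    paths <<- c(paths, p)
    p
  }
  write_annotation_refflat(ann, put("annotation.refFlat"))
  readr::write_tsv(
    tibble::tibble(chrom = names(ann$chrom_sizes),
                   size = unname(ann$chrom_sizes)),
    put("chrom.sizes"), col_names = FALSE, progress = FALSE
  )
  for (cond in design_conditions()) {
    parts <- strsplit(cond, "_", fixed = TRUE)[[1]]
    for (mk in histone_marks()) {
      sub <- pk$peaks[pk$peaks$mark == mk & pk$peaks$age == parts[1] &
                        pk$peaks$group == parts[2], ]
      write_peaks_bed(sub, put(paste0("peaks_", mk, "_", cond, ".bed")))
    }
  }
  for (age in design_ages()) {
    for (mk in histone_marks()) {
      sub <- de$diff[de$diff$mark == mk & de$diff$age == age, ]
      readr::write_tsv(
        sub[, c("chrom", "start", "end", "log2FC", "pvalue", "fdr")],
        put(paste0("diff_", mk, "_", age, ".tsv")), progress = FALSE
      )
    }
    sub <- de$expression[de$expression$age == age, ]
    readr::write_tsv(
      dplyr::rename(sub[, c("gene_id", "log2FC", "fdr",
                            "mean_abundance_control",
                            "mean_abundance_IUGR")],
                    gene = "gene_id"),
      put(paste0("expression_", age, ".tsv")), progress = FALSE
    )
    for (mk in histone_marks()) {
      for (grp in design_groups()) {
        sub <- mo$motifs[mo$motifs$mark == mk & mo$motifs$age == age &
                           mo$motifs$group == grp, ]
        if (nrow(sub) == 0) next
        readr::write_tsv(
          sub[, c("motif_name", "consensus", "pvalue")],
          put(paste0("motifs_", mk, "_", age, "_", grp, ".tsv")),
          progress = FALSE
        )
      }
    }
  }
  readr::write_tsv(pk$manifest, put("manifest_bivalency.tsv"),
                   progress = FALSE)
  readr::write_tsv(de$manifest, put("manifest_regulation.tsv"),
                   progress = FALSE)
  readr::write_tsv(mo$manifest, put("manifest_motifs.tsv"),
                   progress = FALSE)
  config <- tibble::tibble(
    key = c("seed", "n_genes", "n_chroms", "jitter_sd", "noise_sd",
            paste0("state_", names(state_fractions)),
            paste0("class_", names(class_fractions))),
    value = as.character(c(seed, n_genes, n_chroms, jitter_sd, noise_sd,
                           unname(state_fractions),
                           unname(class_fractions)))
  )
  readr::write_tsv(config, put("config.tsv"), progress = FALSE)
  invisible(list(annotation = ann, peaks = pk, regulation = de,
                 motifs = mo, paths = paths))
}

#' @rdname simulate_bundle
#' @export
default_motif_spec <- function() {
  tibble::tibble(
    motif_name = c(paste0("GAIN", 1:9), paste0("LOSS", 1:3),
                   paste0("TRAN", 1:2), paste0("BOTH", 1:2),
                   paste0("NULL", 1:4)),
    mark = c(rep("H3K4me3", 9), rep("H3K27me3", 3),
             rep("H3K4me3", 2), rep("H3K27me3", 2),
             rep(c("H3K4me3", "H3K27me3"), 2)),
    class = c(rep("persistent_gain", 9), rep("persistent_loss", 3),
              rep("transient_gain", 2), rep("both_enriched", 2),
              rep("none", 4))
  )
}
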