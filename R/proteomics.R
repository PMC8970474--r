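#' Comparative two-bait isotope-label enrichment quantification
#'
#' Downstream quantification of a two-bait pull-down with inverted
#' isotope labelling between two replicates: protein ratios from the
#' intensity-weighted average of peptide ratios, replicate orientation
#' (replicate B raw ratios are inverted so that > 1 always means
#' enrichment to the PSD-95 bait), GST normalization, quantification
#' filters (both replicates, minimum peptides, geometric SD < 2,
#' contaminant/bait exclusion), quadrant classification of the two
#' replicate ratios, and fold-enrichment selection (strict > 7 by
#' default, using the weaker replicate).
#'
#' @name proteomics_enrichment
NULL

#' Quantification filter parameters
#'
#' @param min_peptides minimum quantified peptides per replicate.
#' @param max_geometric_sd geometric SD ceiling (strict <).
#' @param require_both_replicates drop proteins missing a replicate.
#' @param fold_threshold fold-enrichment selection threshold (strict >).
#' @param exclusion_list protein ids removed before filtering (baits,
#'   contaminants).
#' @export
quant_filter_params <- function(min_peptides = 2, max_geometric_sd = 2,
                                require_both_replicates = TRUE,
                                fold_threshold = 7,
                                exclusion_list = character(0)) {
  stopifnot(min_peptides >= 1, fold_threshold > 1)
  structure(list(min_peptides = min_peptides,
                 max_geometric_sd = max_geometric_sd,
                 require_both_replicates = require_both_replicates,
                 fold_threshold = fold_threshold,
                 exclusion_list = exclusion_list),
            class = "quant_filter_params")
}

#' Intensity-weighted protein ratio from peptide ratios
#'
#' `sum(intensity * ratio) / sum(intensity)` over the peptides of one
#' protein in one replicate.
#'
#' @param ratios peptide ratios (> 0).
#' @param intensities peptide intensities (> 0).
#' @return list(ratio, n_peptides).
#' @export
protein_ratio <- function(ratios, intensities) {
  stopifnot(length(ratios) == length(intensities), length(ratios) >= 1)
  if (sum(intensities) <= 0) stop("zero total intensity")
  list(ratio = sum(intensities * ratios) / sum(intensities),
       n_peptides = length(ratios))
}

#' Orient replicate ratios to the PSD-95-positive convention
#'
#' Replicates whose labels were switched store inverted raw ratios;
#' those are inverted back so that a ratio > 1 means PSD-95-side
#' enrichment in every replicate.
#'
#' @param ratios named-by-replicate numeric vector (or single value).
#' @param replicate replicate labels, same length.
#' @param inverted_replicates replicates stored in inverted orientation.
#' @export
orient_ratios <- function(ratios, replicate,
                          inverted_replicates = "B") {
  known <- unique(replicate) %in% c("A", "B", inverted_replicates)
  if (!all(known)) {
    stop("unknown replicate label: ",
         paste(setdiff(unique(replicate),
                       c("A", "B", inverted_replicates)), collapse = ", "))
  }
  ifelse(replicate %in% inverted_replicates, 1 / ratios, ratios)
}

#' Normalize oriented ratios by the same-replicate GST ratio
#'
#' @param ratios oriented protein ratios.
#' @param replicate replicate labels, same length.
#' @param gst_ratios named vector of oriented GST ratios per replicate.
#' @export
normalize_by_gst <- function(ratios, replicate, gst_ratios) {
  missing_rep <- setdiff(unique(replicate), names(gst_ratios))
  if (length(missing_rep)) {
    stop("GST ratio missing for replicate: ",
         paste(missing_rep, collapse = ", "))
  }
  ratios / unname(gst_ratios[replicate])
}

#' Geometric standard deviation of positive values
#'
#' `exp(sd(log(x)))` with the sample (n-1) standard deviation; >= 1 by
#' construction, 1 for identical values.
#' @param x positive values.
#' @export
geometric_sd <- function(x) {
  stopifnot(all(x > 0))
  if (length(x) < 2) return(NA_real_)
  exp(stats::sd(log(x)))
}

#' Quantify proteins from a peptide table
#'
#' Runs ratio computation, orientation, and GST normalization; returns
#' one row per protein with per-replicate normalized ratios, peptide
#' counts and the geometric SD across the oriented normalized replicate
#' ratios.
#'
#' @param peptides data.frame with columns protein, peptide, replicate,
#'   ratio, intensity.
#' @param inverted_replicates replicates stored in inverted orientation
#'   (label-switched).
#' @param gst_protein id of the GST normalization protein.
#' @param gsd_level compute the geometric SD across replicate protein
#'   ratios ("replicate", default) or across all oriented peptide
#'   ratios ("peptide").
#' @return data.frame (one row per protein): ratio_A, ratio_B
#'   (normalized, oriented; NA when absent), n_peptides_A/B,
#'   geometric_sd.
#' @export
quantify_proteins <- function(peptides, inverted_replicates = "B",
                              gst_protein = "GST",
                              gsd_level = c("replicate", "peptide")) {
  gsd_level <- match.arg(gsd_level)
  stopifnot(all(c("protein", "replicate", "ratio", "intensity") %in%
                  names(peptides)))
  if (any(peptides$ratio <= 0) || any(peptides$intensity <= 0)) {
    stop("ratios and intensities must be > 0")
  }
  key <- interaction(peptides$protein, peptides$replicate, drop = TRUE)
  agg <- lapply(split(peptides, key), function(df) {
    pr <- protein_ratio(df$ratio, df$intensity)
    data.frame(protein = df$protein[1], replicate = df$replicate[1],
               raw_ratio = pr$ratio, n_peptides = pr$n_peptides)
  })
  agg <- do.call(rbind, agg)
  agg$oriented <- orient_ratios(agg$raw_ratio, agg$replicate,
                                inverted_replicates)
  gst <- agg[agg$protein == gst_protein, ]
  if (!nrow(gst)) stop("GST protein '", gst_protein, "' not found")
  gst_ratios <- stats::setNames(gst$oriented, gst$replicate)
  agg$normalized <- normalize_by_gst(agg$oriented, agg$replicate,
                                     gst_ratios)
  prots <- unique(agg$protein)
  pick <- function(p, rep_id, col) {
    v <- agg[agg$protein == p & agg$replicate == rep_id, col]
    if (length(v)) v[1] else NA_real_
  }
  out <- data.frame(
    protein = prots,
    ratio_A = vapply(prots, pick, numeric(1), "A", "normalized"),
    ratio_B = vapply(prots, pick, numeric(1), "B", "normalized"),
    n_peptides_A = vapply(prots, pick, numeric(1), "A", "n_peptides"),
    n_peptides_B = vapply(prots, pick, numeric(1), "B", "n_peptides"))
  if (gsd_level == "replicate") {
    out$geometric_sd <- vapply(seq_len(nrow(out)), function(i) {
      v <- c(out$ratio_A[i], out$ratio_B[i])
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else geometric_sd(v)
    }, numeric(1))
  } else {
    # peptide-level dispersion of oriented, GST-normalized ratios
    out$geometric_sd <- vapply(out$protein, function(p) {
      df <- peptides[peptides$protein == p, ]
      orr <- orient_ratios(df$ratio, df$replicate, inverted_replicates)
      orr <- normalize_by_gst(orr, df$replicate, gst_ratios)
      geometric_sd(orr)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Apply quantification filters to a protein table
#'
#' Retains proteins quantified in both replicates (when required) with
#' at least `min_peptides` peptides per replicate and a geometric SD
#' strictly below the ceiling; exclusion-list proteins are removed.
#' Removal counts per criterion are reported via `message()`.
#'
#' @param proteins data.frame from [quantify_proteins()].
#' @param params a [quant_filter_params()].
#' @export
apply_quant_filters <- function(proteins,
                                params = quant_filter_params()) {
  p <- proteins
  excl <- p$protein %in% params$exclusion_list
  missing_rep <- is.na(p$ratio_A) | is.na(p$ratio_B)
  few_pep <- (!is.na(p$n_peptides_A) &
                p$n_peptides_A < params$min_peptides) |
    (!is.na(p$n_peptides_B) & p$n_peptides_B < params$min_peptides)
  high_gsd <- !is.na(p$geometric_sd) &
    p$geometric_sd >= params$max_geometric_sd
  drop <- excl | few_pep | high_gsd
  if (params$require_both_replicates) drop <- drop | missing_rep
  message(sprintf(
    paste0("apply_quant_filters: removed %d ",
           "(excluded: %d, single replicate: %d, < %d peptides: %d, ",
           "geometric SD >= %.2g: %d)"),
    sum(drop), sum(excl), sum(missing_rep & !excl),
    params$min_peptides, sum(few_pep), params$max_geometric_sd,
    sum(high_gsd)))
  out <- p[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the enrichment quadrant of a protein
#'
#' Both normalized replicate ratios > 1: PSD-95-enriched (first
#' quadrant on the log-log replicate plot); both < 1: MPP2-enriched
#' (third quadrant); otherwise unassigned. The MPP2-side fold
#' enrichment is the weaker replicate, `min(1/ratio_A, 1/ratio_B)`.
#'
#' @param ratio_a,ratio_b normalized oriented replicate ratios (> 0).
#' @return list(quadrant, mpp2_fold_enrichment, psd95_fold_enrichment).
#' @export
classify_quadrant <- function(ratio_a, ratio_b) {
  if (any(c(ratio_a, ratio_b) <= 0)) stop("ratios must be > 0")
  quadrant <- if (ratio_a > 1 && ratio_b > 1) {
    "PSD95-enriched"
  } else if (ratio_a < 1 && ratio_b < 1) {
    "MPP2-enriched"
  } else {
    "unassigned"
  }
  list(quadrant = quadrant,
       mpp2_fold_enrichment = min(1 / ratio_a, 1 / ratio_b),
       psd95_fold_enrichment = min(ratio_a, ratio_b))
}

#' Add quadrant and fold-enrichment columns to a protein table
#'
#' @param proteins filtered data.frame from [apply_quant_filters()].
#' @export
classify_proteins <- function(proteins) {
  cls <- lapply(seq_len(nrow(proteins)), function(i) {
    classify_quadrant(proteins$ratio_A[i], proteins$ratio_B[i])
  })
  proteins$quadrant <- vapply(cls, `[[`, character(1), "quadrant")
  proteins$mpp2_fold_enrichment <-
    vapply(cls, `[[`, numeric(1), "mpp2_fold_enrichment")
  proteins$psd95_fold_enrichment <-
    vapply(cls, `[[`, numeric(1), "psd95_fold_enrichment")
  proteins
}

#' Select proteins enriched beyond a fold threshold on one side
#'
#' Strict `>` on the weaker replicate's fold enrichment.
#'
#' @param proteins classified table from [classify_proteins()].
#' @param side "MPP2" or "PSD95".
#' @param fold_threshold strict threshold (default 7).
#' @return character vector of protein ids.
#' @export
select_enriched <- function(proteins, side = c("MPP2", "PSD95"),
                            fold_threshold = 7) {
  side <- match.arg(side)
  fold <- if (side == "MPP2") proteins$mpp2_fold_enrichment
          else proteins$psd95_fold_enrichment
  quad <- if (side == "MPP2") "MPP2-enriched" else "PSD95-enriched"
  proteins$protein[proteins$quadrant == quad & fold > fold_threshold]
}

#' Run the full proteomics enrichment pipeline on a peptide table
#'
#' Quantification, orientation, GST normalization, filters and quadrant
#' classification in one call.
#'
#' @inheritParams quantify_proteins
#' @param filter_params a [quant_filter_params()].
#' @return list with `proteins` (classified, filtered table),
#'   `n_quantified` (filter-passing total, GST excluded from the count),
#'   `mpp2_enriched`, `psd95_enriched` (ids beyond the fold threshold).
#' @export
run_proteomics <- function(peptides,
                           filter_params = quant_filter_params(),
                           inverted_replicates = "B",
                           gst_protein = "GST") {
  quant <- quantify_proteins(peptides, inverted_replicates, gst_protein)
  filtered <- apply_quant_filters(quant, filter_params)
  classified <- classify_proteins(filtered)
  counted <- classified[classified$protein != gst_protein, ]
  list(proteins = classified,
       n_quantified = nrow(counted),
       mpp2_enriched = select_enriched(classified, "MPP2",
                                       filter_params$fold_threshold),
       psd95_enriched = select_enriched(classified, "PSD95",
                                        filter_params$fold_threshold))
}

#' Read a peptide quantification TSV
#'
#' Expected columns: protein, peptide, replicate, ratio, intensity.
#' @param path TSV path.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "peptide", "replicate", "ratio", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a protein-level result table as TSV
#' @param proteins classified protein table.
#' @param path output path.
#' @export
write_protein_table <- function(proteins, path) {
  utils::write.table(proteins, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
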