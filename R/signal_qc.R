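#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `time_minutes`, `replicate`.
#' @return validated data frame (see [sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Validate a sample sheet
#'
#' The design is a time course with equal replicate counts per time point
#' and a pre-stimulus time point at 0 minutes.
#'
#' @param df data frame with columns `sample_id`, `time_minutes`,
#'   `replicate`.
#' @return the data frame, ordered by time then replicate.
#' @export
sample_sheet <- function(df) {
  stopifnot(all(c("sample_id", "time_minutes", "replicate") %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (!any(df$time_minutes == 0)) stop("no pre-stimulus (0 min) samples")
  tab <- table(df$time_minutes)
  if (length(unique(tab)) != 1L)
    stop("unequal replicate counts across time points")
  df[order(df$time_minutes, df$replicate), , drop = FALSE]
}

time_points <- function(samples) sort(unique(samples$time_minutes))

n_replicates <- function(samples) sum(samples$time_minutes == samples$time_minutes[1L])

# column indices of one time point, in replicate order
.time_cols <- function(values, samples, t) {
  ids <- samples$sample_id[samples$time_minutes == t]
  match(ids, colnames(values))
}

#' Bundle signal values and detection p-values
#'
#' @param values numeric matrix, probe sets x samples, of normalized log2
#'   intensities.
#' @param detection_p matrix of per-sample detection p-values with identical
#'   dimnames.
#' @param samples a [sample_sheet()] covering all columns.
#' @return object of class `signal_set`.
#' @export
signal_set <- function(values, detection_p, samples) {
  samples <- sample_sheet(samples)
  stopifnot(identical(dim(values), dim(detection_p)),
            identical(dimnames(values), dimnames(detection_p)))
  if (anyNA(values) || anyNA(detection_p)) stop("missing entries in signal tables")
  miss <- setdiff(samples$sample_id, colnames(values))
  if (length(miss)) stop("samples missing from matrix: ", paste(miss, collapse = ","))
  structure(list(values = values, detection_p = detection_p, samples = samples),
            class = "signal_set")
}

#' Read signal and detection tables from TSV
#'
#' @param values_path,detp_path TSV files, first column `ps_id`, remaining
#'   columns one per sample.
#' @param samples_path sample sheet TSV.
#' @return a [signal_set()].
#' @export
read_signal_set <- function(values_path, detp_path, samples_path) {
  rd <- function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  signal_set(rd(values_path), rd(detp_path), read_sample_sheet(samples_path))
}

#' Write a signal set to TSV files
#'
#' @param sig a [signal_set()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the three files written, invisibly.
#' @export
write_signal_set <- function(sig, dir, prefix = "signals") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, p) {
    df <- data.frame(ps_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- file.path(dir, paste0(prefix, c("_values.tsv", "_detp.tsv", "_samples.tsv")))
  wr(sig$values, paths[1L]); wr(sig$detection_p, paths[2L])
  utils::write.table(sig$samples, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Presence mask from detection p-values
#'
#' A probe set is called present at a time point only if its detection
#' p-value is below `alpha_detect` in all replicates of that time point.
#' Probe sets present at no time point are flagged as globally dropped via
#' the `retained` attribute.
#'
#' @param sig a [signal_set()].
#' @param alpha_detect detection threshold, default 0.05.
#' @return logical matrix probe sets x time points, with attribute
#'   `retained` (present at >= 1 time point).
#' @export
presence_mask <- function(sig, alpha_detect = 0.05) {
  stopifnot(alpha_detect > 0, alpha_detect < 1)
  tp <- time_points(sig$samples)
  out <- matrix(FALSE, nrow(sig$detection_p), length(tp),
                dimnames = list(rownames(sig$detection_p), as.character(tp)))
  for (k in seq_along(tp)) {
    cols <- .time_cols(sig$detection_p, sig$samples, tp[k])
    if (anyNA(cols)) stop("missing replicate columns at time ", tp[k])
    out[, k] <- rowSums(sig$detection_p[, cols, drop = FALSE] < alpha_detect) ==
      length(cols)
  }
  attr(out, "retained") <- rowSums(out) > 0L
  out
}

#' Empirical background distribution from constitutive-intron probe sets
#'
#' Pools log2 signal of all constitutive-intron probe sets over all samples
#' into an empirical distribution; its upper quantiles define the signal
#' level that a truly exonic probe set must exceed.
#'
#' @param sig a [signal_set()].
#' @param annot probe-set annotation from [annotate_probesets()].
#' @return object of class `background_distribution` with element
#'   `quantile(q)`.
#' @export
intron_background <- function(sig, annot) {
  ips <- annot$ps_id[annot$label == "constitutive_intron"]
  ips <- intersect(ips, rownames(sig$values))
  if (length(ips) < 50L)
    stop("only ", length(ips),
         " constitutive-intron probe sets; background unidentifiable (need >= 50)")
  v <- sort(as.vector(sig$values[ips, , drop = FALSE]))
  structure(list(values = v, n_ps = length(ips), pooled = TRUE,
                 quantile = function(q) unname(stats::quantile(v, q, type = 7))),
            class = "background_distribution")
}

#' @export
print.background_distribution <- function(x, ...) {
  cat("background_distribution:", x$n_ps, "intron probe sets,",
      length(x$values), "pooled values; median",
      round(x$quantile(0.5), 3), "\n")
  invisible(x)
}

#' Refine putative-exon calls against the intron background
#'
#' A putative-exon probe set is kept as `true_exon` if its replicate-mean
#' log2 signal exceeds the background `q_int` quantile at one or more time
#' points; otherwise it is reclassified as intron-like and excluded from
#' fold-change analysis. Constitutive-intron labels are never touched.
#'
#' @param sig a [signal_set()].
#' @param annot probe-set annotation.
#' @param background from [intron_background()].
#' @param q_int background quantile, default 0.95.
#' @return list with `true_exon` and `reclassified` probe-set id vectors and
#'   `annot` (annotation with added `refined` column:
#'   `true_exon`/`intron_like`/unchanged label).
#' @export
refine_exons <- function(sig, annot, background, q_int = 0.95) {
  stopifnot(q_int > 0, q_int < 1)
  thr <- background$quantile(q_int)
  pe <- annot$ps_id[annot$label == "putative_exon"]
  pe <- intersect(pe, rownames(sig$values))
  tp <- time_points(sig$samples)
  tm <- matrix(NA_real_, length(pe), length(tp))
  for (k in seq_along(tp)) {
    cols <- .time_cols(sig$values, sig$samples, tp[k])
    tm[, k] <- rowMeans(sig$values[pe, cols, drop = FALSE])
  }
  keep <- apply(tm, 1L, max) > thr
  true_exon <- pe[keep]
  reclassified <- pe[!keep]
  annot$refined <- annot$label
  annot$refined[annot$ps_id %in% true_exon] <- "true_exon"
  annot$refined[annot$ps_id %in% reclassified] <- "intron_like"
  list(true_exon = true_exon, reclassified = reclassified,
       threshold = thr, annot = annot)
}

#' QC summary of the exon/intron correction
#'
#' For every gene with both exonic and constitutive-intron probe sets,
#' computes the difference between the average exon signal and the average
#' intron signal, before (all putative exons) and after (true exons only)
#' refinement, and reports the fraction of positive differences.
#'
#' @param sig a [signal_set()].
#' @param annot_before annotation with `label` column.
#' @param annot_after annotation with `refined` column (from
#'   [refine_exons()]).
#' @return list with per-gene difference tables, `fraction_before`,
#'   `fraction_after`, and counts of genes excluded as degenerate.
#' @export
qc_summary <- function(sig, annot_before, annot_after) {
  gene_diff <- function(annot, exon_labels, col) {
    genes <- unique(annot$gene_id)
    d <- rep(NA_real_, length(genes)); names(d) <- genes
    for (g in genes) {
      a <- annot[annot$gene_id == g, , drop = FALSE]
      eps <- intersect(a$ps_id[a[[col]] %in% exon_labels], rownames(sig$values))
      ips <- intersect(a$ps_id[a[[col]] == "constitutive_intron"],
                       rownames(sig$values))
      if (length(eps) == 0L || length(ips) == 0L) next
      d[g] <- mean(sig$values[eps, , drop = FALSE]) -
        mean(sig$values[ips, , drop = FALSE])
    }
    d
  }
  before <- gene_diff(annot_before, "putative_exon", "label")
  after <- gene_diff(annot_after, "true_exon", "refined")
  n_excl <- sum(is.na(before) | is.na(after))
  if (n_excl > 0L)
    message("qc_summary: ", n_excl,
            " genes lacking exon or intron probe sets excluded from fractions")
  list(diff_before = before, diff_after = after,
       fraction_before = mean(before > 0, na.rm = TRUE),
       fraction_after = mean(after > 0, na.rm = TRUE),
       n_genes_excluded = n_excl)
}
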