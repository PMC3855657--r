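# mapping region class -> event type
.REGION_TO_EVENT <- c(alt_first_exon_region = "alt_first_exon",
                      cassette_exon = "cassette_exon",
                      alt_5ss_extension = "alt_5ss",
                      alt_3ss_extension = "alt_3ss",
                      retained_intron = "intron_retention",
                      alt_last_exon_region = "alt_last_exon")

#' Event types recognised by the classifier
#' @export
EVENT_TYPES <- c(unname(.REGION_TO_EVENT), "unclassified")

#' Classify a TIV event by the region classes of its deviating probe sets
#'
#' Each deviating probe set votes with the region class covering the
#' largest part of its interval in the gene's [region_classes()] partition;
#' constitutive classes carry no vote. The event type is the majority vote,
#' mapped to the canonical alternative-transcript taxonomy; ties or
#' constitutive-only events are `unclassified`.
#'
#' @param event one row of the [call_tiv()] data frame (or a list with
#'   `gene_id` and `ps_ids`).
#' @param model the gene's `gene_model`.
#' @param annot probe-set annotation with `start`/`end` columns.
#' @return one of [EVENT_TYPES].
#' @export
classify_event <- function(event, model, annot) {
  ps <- strsplit(event$ps_ids, ",", fixed = TRUE)[[1L]]
  a <- annot[match(ps, annot$ps_id), , drop = FALSE]
  if (anyNA(a$ps_id)) stop("event probe sets missing from annotation")
  rc <- region_classes(model)
  alt_classes <- names(.REGION_TO_EVENT)
  votes <- character(0)
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a$end[i], rc$end) - pmax(a$start[i], rc$start)
    ov[ov < 0] <- 0
    # total overlap per alternative class; constitutive bases carry no vote
    by_class <- vapply(alt_classes, function(cl) sum(ov[rc$class == cl]),
                       numeric(1))
    if (all(by_class == 0)) next
    votes <- c(votes, alt_classes[which.max(by_class)])
  }
  if (length(votes) == 0L) return("unclassified")
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return("unclassified")
  unname(.REGION_TO_EVENT[names(tab)[1L]])
}

#' Classify all events of a call set
#'
#' @param events data frame from [call_tiv()].
#' @param models named list of `gene_model` objects.
#' @param annot probe-set annotation.
#' @return `events` with an added `event_type` column.
#' @export
classify_events <- function(events, models, annot) {
  events$event_type <- vapply(seq_len(nrow(events)), function(i)
    classify_event(events[i, ], models[[events$gene_id[i]]], annot),
    character(1))
  events
}

#' Short/long isoform-ratio time profile
#'
#' The per-time log2 ratio is the median fold change of the short-isoform-
#' specific probe sets minus the median fold change of the long-isoform-
#' specific probe sets; an increasing profile means the short isoforms gain
#' relative abundance after stimulation. Exactly antisymmetric under
#' swapping the two sets.
#'
#' @param fc an `fc_table`.
#' @param gene_id gene identifier (metadata).
#' @param short_ids,long_ids disjoint, non-empty probe-set id vectors
#'   specific to the short and long isoforms.
#' @return object of class `isoform_ratio_profile` with `times` and
#'   `ratio` (0 at the pre-stimulus time point by construction).
#' @export
isoform_ratio <- function(fc, gene_id, short_ids, long_ids) {
  if (length(short_ids) == 0L || length(long_ids) == 0L)
    stop("empty isoform-specific probe-set set")
  if (length(intersect(short_ids, long_ids)) > 0L)
    stop("short and long probe-set sets overlap")
  med <- function(ids) apply(fc$fc[ids, , drop = FALSE], 2L, stats::median,
                             na.rm = TRUE)
  ratio <- med(short_ids) - med(long_ids)
  structure(list(gene_id = gene_id, times = fc$times, ratio = ratio,
                 short_ids = short_ids, long_ids = long_ids),
            class = "isoform_ratio_profile")
}

#' @export
print.isoform_ratio_profile <- function(x, ...) {
  cat("isoform_ratio_profile for", x$gene_id, "\n")
  print(round(stats::setNames(x$ratio, x$times), 3))
  invisible(x)
}

#' Rank TIV events
#'
#' Orders by minimal q-value ascending, then by maximal absolute deviation
#' descending, then by gene id (lexicographic) for full determinism.
#'
#' @param events data frame from [call_tiv()].
#' @return the events, reordered.
#' @export
rank_events <- function(events) {
  o <- order(events$q_min, -events$max_abs_delta, events$gene_id,
             events$start_idx)
  out <- events[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
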