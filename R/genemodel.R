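#' Construct a gene model from isoform exon structures
#'
#' A gene model holds the exon structures of all annotated isoforms of one
#' gene on a fixed strand, in 0-based half-open coordinates. All derived
#' region logic (constitutive introns, region classes) is computed from it.
#'
#' @param gene_id character scalar.
#' @param strand `"+"` or `"-"`. Strand affects only the orientation of
#'   "first"/"last" exons, never interval arithmetic.
#' @param isoforms named list; each element is a 2-column matrix or
#'   data frame of exon `(start, end)` rows, 0-based half-open,
#'   non-overlapping within the isoform.
#' @param chrom chromosome/contig identifier (metadata only).
#' @return An object of class `gene_model`.
#' @examples
#' gm <- gene_model("g1", "+", list(t1 = cbind(c(0, 200), c(100, 300))))
#' constitutive_introns(gm)
#' @export
gene_model <- function(gene_id, strand, isoforms, chrom = "chr1") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(isoforms) < 1L) stop("gene ", gene_id, " has no isoforms")
  if (is.null(names(isoforms)) || anyNA(names(isoforms)) || any(names(isoforms) == ""))
    names(isoforms) <- paste0(gene_id, ".t", seq_along(isoforms))
  isoforms <- lapply(isoforms, function(ex) {
    ex <- as.matrix(ex)
    if (nrow(ex) == 0L) stop("isoform with no exons in gene ", gene_id)
    m <- iv(ex[, 1L], ex[, 2L])
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
      stop("overlapping exons within one isoform of gene ", gene_id)
    iv_union(m)  # normalize abutting exons into one
  })
  structure(list(gene_id = gene_id, strand = strand, chrom = chrom,
                 isoforms = isoforms),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "(", x$strand, ")",
      length(x$isoforms), "isoform(s), span",
      paste(gene_span(x), collapse = "-"), "\n")
  invisible(x)
}

#' Genomic span of a gene model
#'
#' @param model a `gene_model`.
#' @return integer vector `c(start, end)` covering all isoforms.
#' @export
gene_span <- function(model) {
  s <- min(vapply(model$isoforms, function(m) m[1L, 1L], integer(1)))
  e <- max(vapply(model$isoforms, function(m) m[nrow(m), 2L], integer(1)))
  c(start = s, end = e)
}

#' Union of all exonic bases of a gene model
#'
#' @param model a `gene_model`.
#' @return disjoint interval matrix (columns `start`, `end`).
#' @export
exon_union <- function(model) {
  iv_union(do.call(rbind, model$isoforms))
}

#' First (5'-most) exon of each isoform
#'
#' @param model a `gene_model`.
#' @return named list of one-row interval matrices, one per isoform.
#' @export
first_exons <- function(model) {
  lapply(model$isoforms, function(m) {
    if (model$strand == "+") m[1L, , drop = FALSE] else m[nrow(m), , drop = FALSE]
  })
}

#' Last (3'-most) exon of each isoform
#'
#' @param model a `gene_model`.
#' @return named list of one-row interval matrices, one per isoform.
#' @export
last_exons <- function(model) {
  lapply(model$isoforms, function(m) {
    if (model$strand == "+") m[nrow(m), , drop = FALSE] else m[1L, , drop = FALSE]
  })
}

#' Constitutive introns of a gene model
#'
#' A constitutive intron is a maximal region that is intronic in every
#' isoform: inside each isoform's transcribed span and outside its exons.
#' Probe sets falling inside constitutive introns measure pre-mRNA /
#' background signal and anchor the background distribution used to refine
#' exon calls.
#'
#' @param model a `gene_model`.
#' @return disjoint interval matrix (possibly 0 rows).
#' @export
constitutive_introns <- function(model) {
  introns <- NULL
  for (ex in model$isoforms) {
    span <- cbind(ex[1L, 1L], ex[nrow(ex), 2L])
    intr <- iv_setdiff(span, ex)
    introns <- if (is.null(introns)) intr else iv_intersect(introns, intr)
    if (nrow(introns) == 0L) return(iv_empty())
  }
  introns
}

# region class levels, in precedence-free display order
REGION_CLASSES <- c("constitutive_exon", "alt_first_exon_region",
                    "cassette_exon", "alt_5ss_extension",
                    "alt_3ss_extension", "retained_intron",
                    "alt_last_exon_region", "constitutive_intron")

#' Partition a gene span into alternative-transcript region classes
#'
#' Every base of the gene span is assigned to exactly one class based on
#' which isoforms carry it as exonic and where it sits relative to
#' transcription starts/ends and shared exon boundaries:
#' \itemize{
#'  \item `constitutive_exon` - exonic in every isoform (also the fallback
#'    for alternative exonic bases matching no specific pattern);
#'  \item `alt_first_exon_region` - exonic in a subset of isoforms and
#'    either upstream of the transcription start of all other isoforms or
#'    inside the first exon of every isoform carrying it;
#'  \item `alt_last_exon_region` - the 3' mirror image;
#'  \item `retained_intron` - exonic in a subset whose exon spans a complete
#'    intron of the remaining isoforms;
#'  \item `cassette_exon` - a complete internal exon of the carrying subset,
#'    intronic in the rest;
#'  \item `alt_5ss_extension` / `alt_3ss_extension` - exonic bases extending
#'    a shared exon past its donor (5'ss) or acceptor (3'ss) boundary;
#'  \item `constitutive_intron` - bases exonic in no isoform.
#' }
#' First/last-exon rules take precedence over the splicing rules so that
#' alternative-promoter regions are never typed as cassettes.
#'
#' @param model a `gene_model`.
#' @return data frame with columns `start`, `end`, `class`; rows tile the
#'   gene span with no gaps or overlaps.
#' @export
region_classes <- function(model) {
  isos <- model$isoforms
  n <- length(isos)
  span <- gene_span(model)
  bp <- sort(unique(c(span, unlist(lapply(isos, as.vector)))))
  seg_s <- bp[-length(bp)]
  seg_e <- bp[-1L]
  cls <- character(length(seg_s))
  for (k in seq_along(seg_s)) {
    cls[k] <- .classify_segment(isos, model$strand, seg_s[k], seg_e[k])
  }
  # merge adjacent segments of equal class
  keep <- c(TRUE, cls[-1L] != cls[-length(cls)])
  grp <- cumsum(keep)
  data.frame(start = as.integer(tapply(seg_s, grp, min)),
             end = as.integer(tapply(seg_e, grp, max)),
             class = cls[keep],
             stringsAsFactors = FALSE)
}

# classify one atomic segment [s, e) that crosses no exon boundary
.classify_segment <- function(isos, strand, s, e) {
  n <- length(isos)
  exonic <- vapply(isos, function(m) any(m[, 1L] <= s & e <= m[, 2L]), logical(1))
  if (all(exonic)) return("constitutive_exon")
  if (!any(exonic)) return("constitutive_intron")
  E <- which(exonic); Oth <- which(!exonic)

  span_s <- vapply(isos, function(m) m[1L, 1L], integer(1))
  span_e <- vapply(isos, function(m) m[nrow(m), 2L], integer(1))
  # transcription-direction helpers (strand flips upstream/downstream)
  upstream_of_tss <- function(j)
    if (strand == "+") e <= span_s[j] else s >= span_e[j]
  downstream_of_tes <- function(j)
    if (strand == "+") s >= span_e[j] else e <= span_s[j]
  in_first <- function(i) {
    fe <- if (strand == "+") isos[[i]][1L, ] else isos[[i]][nrow(isos[[i]]), ]
    fe[1L] <= s && e <= fe[2L]
  }
  in_last <- function(i) {
    le <- if (strand == "+") isos[[i]][nrow(isos[[i]]), ] else isos[[i]][1L, ]
    le[1L] <= s && e <= le[2L]
  }

  if (all(vapply(Oth, upstream_of_tss, logical(1))) ||
      all(vapply(E, in_first, logical(1))))
    return("alt_first_exon_region")
  if (all(vapply(Oth, downstream_of_tes, logical(1))) ||
      all(vapply(E, in_last, logical(1))))
    return("alt_last_exon_region")

  # remaining specific classes require every non-carrier to be intronic here
  intronic_in <- function(j) span_s[j] <= s && e <= span_e[j]
  if (all(vapply(Oth, intronic_in, logical(1)))) {
    # exon of each carrier containing the segment
    ex_of <- lapply(E, function(i) {
      m <- isos[[i]]
      m[which(m[, 1L] <= s & e <= m[, 2L])[1L], ]
    })
    # intron of each non-carrier containing the segment
    intr_of <- lapply(Oth, function(j) {
      m <- isos[[j]]
      idx <- findInterval(s, m[, 1L])  # exon before the segment
      c(m[idx, 2L], m[idx + 1L, 1L])
    })
    # retained intron: carrier exon strictly spans the full intron of every
    # non-carrier
    if (length(intr_of) > 0L &&
        all(vapply(seq_along(ex_of), function(a)
          all(vapply(intr_of, function(uv)
            ex_of[[a]][1L] < uv[1L] && ex_of[[a]][2L] > uv[2L], logical(1))),
          logical(1))))
      return("retained_intron")
    # cassette: the segment is exactly a complete internal exon of carriers
    full_exon <- all(vapply(ex_of, function(x)
      x[1L] == s && x[2L] == e, logical(1)))
    internal <- all(vapply(E, function(i) {
      m <- isos[[i]]
      m[1L, 1L] < s && m[nrow(m), 2L] > e
    }, logical(1)))
    if (full_exon && internal) return("cassette_exon")
    # splice-site extensions of a shared exon boundary
    shared_at <- function(pos)
      all(vapply(isos, function(m)
        any(m[, 1L] <= pos & pos + 1L <= m[, 2L]), logical(1)))
    ext_high <- shared_at(e) &&
      all(vapply(ex_of, function(x) x[2L] > e, logical(1)))
    ext_low <- s > 0L && shared_at(s - 1L) &&
      all(vapply(ex_of, function(x) x[1L] < s, logical(1)))
    if (ext_high)  # segment sits on the low-coordinate side of a shared exon
      return(if (strand == "+") "alt_3ss_extension" else "alt_5ss_extension")
    if (ext_low)
      return(if (strand == "+") "alt_5ss_extension" else "alt_3ss_extension")
  }
  "constitutive_exon"  # alternative exonic, no specific pattern
}

#' Annotate probe sets against gene models
#'
#' Assigns each probe set the label `constitutive_intron` (interval fully
#' inside a constitutive intron), `putative_exon` (fully inside the exon
#' union), or `ambiguous` (straddles a boundary; excluded downstream).
#' Probe sets mapped to unknown genes are dropped with a logged count.
#'
#' @param ps_table data frame with columns `ps_id`, `gene_id`, `start`,
#'   `end` (0-based half-open) and optionally `chrom`, `strand`, `tier`.
#' @param models named list of `gene_model` objects (names = gene ids).
#' @return the input rows for known genes with an added `label` column.
#' @export
annotate_probesets <- function(ps_table, models) {
  stopifnot(all(c("ps_id", "gene_id", "start", "end") %in% names(ps_table)))
  known <- ps_table$gene_id %in% names(models)
  if (any(!known))
    message("annotate_probesets: dropped ", sum(!known),
            " probe sets mapped to unknown genes")
  ps <- ps_table[known, , drop = FALSE]
  ps$label <- "ambiguous"
  for (g in unique(ps$gene_id)) {
    idx <- which(ps$gene_id == g)
    m <- models[[g]]
    eu <- exon_union(m)
    ci <- constitutive_introns(m)
    s <- ps$start[idx]; e <- ps$end[idx]
    lab <- rep("ambiguous", length(idx))
    lab[iv_contains(eu, s, e)] <- "putative_exon"
    lab[iv_contains(ci, s, e)] <- "constitutive_intron"
    ps$label[idx] <- lab
  }
  rownames(ps) <- NULL
  ps
}

#' Load gene models from simplified JSON or GTF
#'
#' The JSON dialect is a list of objects with fields `gene_id`, `strand`,
#' `chrom` and `isoforms` (a map isoform id -> list of `[start, end)` exon
#' pairs). GTF input (exon features with `gene_id`/`transcript_id`
#' attributes, 1-based inclusive coordinates) requires the `rtracklayer`
#' package and is converted to 0-based half-open coordinates. Isoform
#' records with overlapping exons are rejected with a warning; a gene whose
#' isoforms are all rejected is an error.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.gtf`/`.gff`).
#' @return named list of `gene_model` objects.
#' @export
load_gene_models <- function(path) {
  if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE))
    return(.load_gene_models_gtf(path))
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  models <- list()
  for (r in recs) {
    isos <- list()
    for (tid in names(r$isoforms)) {
      ex <- do.call(rbind, lapply(r$isoforms[[tid]], unlist))
      ok <- tryCatch({ isos[[tid]] <- iv(ex[, 1L], ex[, 2L]); TRUE },
                     error = function(e) FALSE)
      if (ok && nrow(isos[[tid]]) > 1L &&
          any(isos[[tid]][-1L, 1L] < isos[[tid]][-nrow(isos[[tid]]), 2L])) {
        warning("rejected isoform ", tid, " of gene ", r$gene_id,
                ": overlapping exons")
        isos[[tid]] <- NULL
      }
    }
    if (length(isos) == 0L) stop("gene ", r$gene_id, " has no valid isoforms")
    models[[r$gene_id]] <-
      gene_model(r$gene_id, r$strand, isos, chrom = r$chrom %||% "chr1")
  }
  models
}

.load_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GTF input requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  df <- data.frame(gene_id = gr$gene_id,
                   tx = gr$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  models <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    isos <- lapply(split(sub, sub$tx), function(x) cbind(x$start, x$end))
    models[[g]] <- gene_model(g, sub$strand[1L], isos, chrom = sub$chrom[1L])
  }
  models
}

#' Write gene models to the simplified JSON dialect
#'
#' Round-trips exactly with [load_gene_models()].
#'
#' @param models named list of `gene_model` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  recs <- lapply(models, function(m) {
    list(gene_id = m$gene_id, strand = m$strand, chrom = m$chrom,
         isoforms = lapply(m$isoforms, function(ex)
           lapply(seq_len(nrow(ex)), function(i) as.integer(ex[i, ]))))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
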