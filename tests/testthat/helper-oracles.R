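# Independent brute-force oracles and small fixture builders.
# Oracles work base-by-base on explicit membership tables, never through
# the package's interval arithmetic.

base_exonic <- function(exons, b) any(exons[, 1] <= b & b < exons[, 2])

# base-wise constitutive introns: intronic (in-span, non-exonic) in every
# isoform
oracle_constitutive_introns <- function(model) {
  sp <- gene_span(model)
  bases <- sp[1]:(sp[2] - 1L)
  ok <- rep(TRUE, length(bases))
  for (ex in model$isoforms) {
    span_s <- ex[1, 1]; span_e <- ex[nrow(ex), 2]
    intr <- vapply(bases, function(b)
      b >= span_s && b < span_e && !base_exonic(ex, b), logical(1))
    ok <- ok & intr
  }
  runs_to_intervals(bases, ok)
}

runs_to_intervals <- function(bases, flag) {
  if (!any(flag)) return(cbind(start = integer(0), end = integer(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = bases[starts[keep]], end = bases[ends[keep]] + 1L)
}

# base-wise region classifier: reimplements the documented membership-
# pattern rules directly on a per-base membership matrix
oracle_region_classes_bases <- function(model) {
  isos <- model$isoforms
  strand <- model$strand
  n <- length(isos)
  sp <- gene_span(model)
  bases <- sp[1]:(sp[2] - 1L)
  memb <- vapply(isos, function(ex)
    vapply(bases, function(b) base_exonic(ex, b), logical(1)),
    logical(length(bases)))
  memb <- matrix(memb, ncol = n)
  span_s <- vapply(isos, function(m) m[1, 1], numeric(1))
  span_e <- vapply(isos, function(m) m[nrow(m), 2], numeric(1))
  pat <- apply(memb, 1, paste, collapse = "")
  all_exonic_at <- function(b) {
    i <- b - sp[1] + 1L
    i >= 1L && i <= length(bases) && all(memb[i, ])
  }
  cls <- character(length(bases))
  for (i in seq_along(bases)) {
    b <- bases[i]
    E <- which(memb[i, ]); Oth <- setdiff(seq_len(n), E)
    if (length(E) == n) { cls[i] <- "constitutive_exon"; next }
    if (length(E) == 0L) { cls[i] <- "constitutive_intron"; next }
    upstream <- vapply(Oth, function(j)
      if (strand == "+") b < span_s[j] else b >= span_e[j], logical(1))
    in_first <- vapply(E, function(k) {
      fe <- if (strand == "+") isos[[k]][1, ] else isos[[k]][nrow(isos[[k]]), ]
      fe[1] <= b && b < fe[2]
    }, logical(1))
    if (all(upstream) || all(in_first)) { cls[i] <- "alt_first_exon_region"; next }
    downstream <- vapply(Oth, function(j)
      if (strand == "+") b >= span_e[j] else b < span_s[j], logical(1))
    in_last <- vapply(E, function(k) {
      le <- if (strand == "+") isos[[k]][nrow(isos[[k]]), ] else isos[[k]][1, ]
      le[1] <= b && b < le[2]
    }, logical(1))
    if (all(downstream) || all(in_last)) { cls[i] <- "alt_last_exon_region"; next }
    intronic <- vapply(Oth, function(j)
      b >= span_s[j] && b < span_e[j], logical(1))
    if (length(Oth) > 0L && all(intronic)) {
      ex_of <- lapply(E, function(k) {
        m <- isos[[k]]
        m[m[, 1] <= b & b < m[, 2], ]
      })
      intr_of <- lapply(Oth, function(j) {
        m <- isos[[j]]
        prev <- max(m[m[, 2] <= b, 2])
        nxt <- min(m[m[, 1] > b, 1])
        c(prev, nxt)
      })
      retained <- all(vapply(ex_of, function(x)
        all(vapply(intr_of, function(uv)
          x[1] < uv[1] && x[2] > uv[2], logical(1))), logical(1)))
      if (retained) { cls[i] <- "retained_intron"; next }
      # cassette: all carrier exons identical, a full exon, internal,
      # intronic throughout in non-carriers
      ex0 <- ex_of[[1]]
      same <- all(vapply(ex_of, function(x) all(x == ex0), logical(1)))
      internal <- all(vapply(E, function(k) {
        m <- isos[[k]]
        m[1, 1] < ex0[1] && m[nrow(m), 2] > ex0[2]
      }, logical(1)))
      oth_intronic_all <- all(vapply(Oth, function(j)
        !any(vapply(ex0[1]:(ex0[2] - 1L), function(bb)
          base_exonic(isos[[j]], bb), logical(1))), logical(1)))
      pattern_const <- length(unique(pat[(ex0[1]:(ex0[2] - 1L)) - sp[1] + 1L])) == 1L
      if (same && internal && oth_intronic_all && pattern_const) {
        cls[i] <- "cassette_exon"; next
      }
      # extensions: walk to the first position where the membership pattern
      # changes; if that flank is exonic in all isoforms the base extends a
      # shared exon boundary
      q <- b
      while (q < sp[2] - 1L && pat[q - sp[1] + 2L] == pat[i]) q <- q + 1L
      p <- b
      while (p > sp[1] && pat[p - sp[1]] == pat[i]) p <- p - 1L
      if (all_exonic_at(q + 1L)) {
        cls[i] <- if (strand == "+") "alt_3ss_extension" else "alt_5ss_extension"
        next
      }
      if (all_exonic_at(p - 1L)) {
        cls[i] <- if (strand == "+") "alt_5ss_extension" else "alt_3ss_extension"
        next
      }
    }
    cls[i] <- "constitutive_exon"
  }
  list(bases = bases, class = cls)
}

# expand a region_classes() partition to one class per base
expand_region_classes <- function(rc, span) {
  bases <- span[1]:(span[2] - 1L)
  cls <- rep(NA_character_, length(bases))
  for (i in seq_len(nrow(rc)))
    cls[(rc$start[i]:(rc$end[i] - 1L)) - span[1] + 1L] <- rc$class[i]
  cls
}

# base-wise classify_event: per probe set, majority base class; majority
# vote over probe sets
oracle_classify_event <- function(event, model, annot) {
  orc <- oracle_region_classes_bases(model)
  map <- c(alt_first_exon_region = "alt_first_exon",
           cassette_exon = "cassette_exon",
           alt_5ss_extension = "alt_5ss", alt_3ss_extension = "alt_3ss",
           retained_intron = "intron_retention",
           alt_last_exon_region = "alt_last_exon")
  ps <- strsplit(event$ps_ids, ",")[[1]]
  votes <- character(0)
  for (id in ps) {
    a <- annot[annot$ps_id == id, ]
    bcls <- orc$class[orc$bases >= a$start & orc$bases < a$end]
    counts <- vapply(names(map), function(cl) sum(bcls == cl), numeric(1))
    if (all(counts == 0)) next
    votes <- c(votes, names(map)[which.max(counts)])
  }
  if (length(votes) == 0L) return("unclassified")
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return("unclassified")
  unname(map[names(tab)[1]])
}

# random gene models exercising all structure kinds: a slot grid of exons
# with random subsets, boundary extensions, and adjacent-slot merges
random_gene_model <- function(id, n_iso = sample(2:4, 1), n_slots = 6L) {
  slot <- function(k) c(k * 120L, k * 120L + 60L)
  isos <- list()
  for (j in seq_len(n_iso)) {
    ks <- sort(sample(0:(n_slots - 1L), sample(seq_len(n_slots), 1)))
    ex <- t(vapply(ks, slot, integer(2)))
    if (nrow(ex) >= 2L && stats::runif(1) < 0.25) {
      i <- sample(nrow(ex) - 1L, 1)
      if (ex[i + 1L, 1] - ex[i, 2] == 60L) {  # merge across one gap
        ex[i, 2] <- ex[i + 1L, 2]
        ex <- ex[-(i + 1L), , drop = FALSE]
      }
    }
    if (stats::runif(1) < 0.3) {
      i <- sample(nrow(ex), 1)
      ex[i, 2] <- ex[i, 2] + 30L
    }
    if (stats::runif(1) < 0.3) {
      i <- sample(nrow(ex), 1)
      ex[i, 1] <- ex[i, 1] - 30L
    }
    isos[[paste0("t", j)]] <- ex
  }
  gene_model(id, sample(c("+", "-"), 1), isos)
}

# minimal signal_set builder: values given as a probe set x (time,rep)
# array via a mean matrix plus noise
make_signal_set <- function(mean_mat, times, R = 3, sd = 0, detp = 0.001,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ps <- nrow(mean_mat)
  samples <- data.frame(
    sample_id = as.vector(outer(seq_len(R), times,
                                function(r, t) sprintf("t%03d_r%d", t, r))),
    time_minutes = rep(times, each = R),
    replicate = rep(seq_len(R), length(times)))
  values <- matrix(NA_real_, n_ps, nrow(samples),
                   dimnames = list(rownames(mean_mat), samples$sample_id))
  for (k in seq_along(times)) {
    cols <- (k - 1L) * R + seq_len(R)
    values[, cols] <- mean_mat[, k] + matrix(rnorm(n_ps * R, 0, sd), n_ps, R)
  }
  dp <- matrix(detp, n_ps, ncol(values), dimnames = dimnames(values))
  signal_set(values, dp, samples)
}

# constant-sd noise model without fitting
flat_noise_model <- function(sd) {
  structure(list(intensity = c(0, 20), sd = c(sd, sd), n_replicates = 3L),
            class = "noise_model")
}
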