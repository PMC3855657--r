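# Ground-truthed synthetic data for every pipeline stage: gene models with
# probe layouts, signal time courses with injected differential expression
# and TIV, scratch-assay image series, and screen plates.

#' Simulation parameters
#'
#' The defaults state the emulated experimental world: biological
#' triplicates at seven time points (0, 20, 40, 60, 120, 240, 480 min);
#' genes carrying 8 exonic and 3 constitutive-intron probe sets; intronic
#' signal offset -3 log2 below the exonic baseline; replicate noise
#' declining with intensity; injected gene-level fold changes and TIV
#' deviations of |1| log2 sustained over 3 adjacent time points; a
#' 6 x 4-tile scratch-image series; and an 11-replicate screen plate with
#' a 35-gene design (29/5/1 genes with 2/3/4 isoforms; two oligos per
#' isoform = 154 isoform-specific oligos plus 35 gene-level pools).
#'
#' @param seed integer seed; fully determines all emitted data.
#' @param n_genes number of genes in the array simulation.
#' @param ... overrides for any default listed above (see source for the
#'   full field list).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_genes = 200L, ...) {
  spec <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    times = c(0, 20, 40, 60, 120, 240, 480), replicates = 3L,
    baseline_mean = 8, baseline_sd = 0.15, ps_sd = 0.1,
    intron_offset = -3,
    noise_curve = list(intensity = c(3, 8), sd = c(0.6, 0.2)),
    de_fraction = 0.1, de_log2fc = 1.0,
    tiv_fraction = 0.1, tiv_delta = 1.0, tiv_run = 3L,
    event_types = c("alt_first_exon", "cassette_exon", "alt_5ss",
                    "alt_3ss", "intron_retention"),
    n_intron_ps = 3L, decoy_prob = 0.2,
    detect_mid = 5.0, detect_k = 4, detect_jitter = 0.15,
    # scratch assay
    tile_nrow = 6L, tile_ncol = 4L, tile_h = 60L, tile_w = 80L,
    gap0 = 160, closure_speed = 3, scratch_times_h = seq(0, 20, by = 4),
    sheet_level = 0.55, texture_amp = 0.35, noise_level = 0.02,
    # screen
    screen_iso_counts = c(rep(2L, 29L), rep(3L, 5L), 4L),
    screen_replicates = 11L, n_control_wells = 11L,
    amd0 = 150, amd_sd = 15)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) stop("unknown spec fields: ", paste(unknown, collapse = ","))
  spec[names(dots)] <- dots
  stopifnot(spec$de_fraction >= 0, spec$de_fraction <= 1,
            spec$tiv_fraction >= 0, spec$tiv_fraction <= 1,
            spec$decoy_prob >= 0, spec$decoy_prob <= 1)
  structure(spec, class = "simulation_spec")
}

sigma_at <- function(spec, intensity) {
  nc <- spec$noise_curve
  stats::approx(nc$intensity, nc$sd, xout = intensity, rule = 2)$y
}

# canonical single-event gene templates; unit layout with exons of width
# 100 spaced 200 apart.  Each template yields 8 exonic probe-set regions,
# one of which (for TIV types) is the event region.
.gene_template <- function(type, strand) {
  ex <- function(k) c(k * 200L, k * 200L + 100L)  # exon k
  rbindv <- function(...) do.call(rbind, list(...))
  mat <- function(ks) rbindv(t(vapply(ks, ex, integer(2))))
  mirror_type <- function(tp) tp  # templates below are built strand-aware
  if (type %in% c("none", "de")) {
    isos <- list(t1 = mat(0:7))
    ps_regions <- mat(0:7); event <- NULL
  } else if (type == "alt_first_exon") {
    if (strand == "+") {
      a <- ex(0); b <- ex(1); shared <- 2:7
    } else {
      a <- ex(7); b <- ex(6); shared <- 0:5
    }
    isos <- list(t1 = iv(c(a[1], mat(shared)[, 1]), c(a[2], mat(shared)[, 2])),
                 t2 = iv(c(b[1], mat(shared)[, 1]), c(b[2], mat(shared)[, 2])))
    ps_regions <- rbind(a, b, mat(shared)); event <- b
  } else if (type == "alt_last_exon") {
    if (strand == "+") {
      a <- ex(6); b <- ex(7); shared <- 0:5
    } else {
      a <- ex(1); b <- ex(0); shared <- 2:7
    }
    isos <- list(t1 = iv(c(mat(shared)[, 1], a[1]), c(mat(shared)[, 2], a[2])),
                 t2 = iv(c(mat(shared)[, 1], b[1]), c(mat(shared)[, 2], b[2])))
    ps_regions <- rbind(a, b, mat(shared)); event <- b
  } else if (type == "cassette_exon") {
    isos <- list(t1 = mat(0:7), t2 = mat(setdiff(0:7, 3L)))
    ps_regions <- mat(0:7); event <- ex(3)
  } else if (type %in% c("alt_5ss", "alt_3ss")) {
    e3 <- ex(3)
    # extension past the donor (5'ss) or acceptor (3'ss) of shared exon 3
    donor_high <- (type == "alt_5ss") == (strand == "+")
    x <- if (donor_high) c(e3[2], e3[2] + 60L) else c(e3[1] - 60L, e3[1])
    ext3 <- if (donor_high) c(e3[1], x[2]) else c(x[1], e3[2])
    t1 <- mat(0:6); t1[4L, ] <- ext3
    isos <- list(t1 = iv(t1[, 1], t1[, 2]), t2 = mat(0:6))
    ps_regions <- rbind(mat(0:6), x); event <- x
  } else if (type == "intron_retention") {
    t1 <- mat(setdiff(0:6, 4L)); t1[4L, ] <- c(ex(3)[1], ex(4)[2])
    isos <- list(t1 = iv(t1[, 1], t1[, 2]), t2 = mat(0:6))
    x <- c(ex(3)[2], ex(4)[1])
    ps_regions <- rbind(mat(0:6), x); event <- x
  } else stop("unknown template type: ", type)
  rownames(ps_regions) <- NULL
  list(isoforms = isos, ps_regions = ps_regions, event_region = event)
}

# probe-set interval inside a region: [start+20, start+40) for width-100
# exons, centered for narrow regions
.ps_in_region <- function(region) {
  w <- region[2] - region[1]
  if (w >= 60L) c(region[1] + 20L, region[1] + 40L)
  else c(region[1] + (w - 20L) %/% 2L, region[1] + (w - 20L) %/% 2L + 20L)
}

#' Simulate gene models with probe-set layouts and ground truth
#'
#' Each gene is assigned a status (`null`, `de`, or a TIV event type) and
#' built from a canonical one- or two-isoform template engineered to
#' contain the region class its event type requires. Every gene carries 8
#' exonic probe sets (one inside the event region for TIV genes), 3
#' probe sets inside constitutive introns, and, with probability
#' `decoy_prob`, one decoy "putative exon" probe set that will emit
#' intron-level signal.
#'
#' @param spec a [simulation_spec()].
#' @return list with `models` (named list of `gene_model`), `ps`
#'   (probe-set annotation table), and `truth` (per-gene status table plus
#'   per-probe-set `kind`: exon/event/intron/decoy).
#' @export
simulate_gene_models <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_genes
  n_tiv <- round(spec$tiv_fraction * n)
  n_de <- round(spec$de_fraction * n)
  types <- rep(spec$event_types, length.out = max(n_tiv, 1L))[seq_len(n_tiv)]
  status <- c(types, rep("de", n_de), rep("none", n - n_tiv - n_de))
  status <- sample(status)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  gene_ids <- sprintf("g%04d", seq_len(n))

  models <- vector("list", n); names(models) <- gene_ids
  offset_step <- 5000L
  has_decoy <- stats::runif(n) < spec$decoy_prob
  # templates are identical per (status, strand) up to a coordinate offset:
  # prepare each combination once
  tpl_cache <- list()
  prepared <- function(type, strand) {
    key <- paste(type, strand)
    if (!is.null(tpl_cache[[key]])) return(tpl_cache[[key]])
    tpl <- .gene_template(type, strand)
    model0 <- gene_model("tpl", strand, tpl$isoforms, chrom = "chr1")
    ints <- t(apply(tpl$ps_regions, 1L, .ps_in_region))
    kind <- rep("exon", nrow(ints))
    if (!is.null(tpl$event_region)) {
      inside <- ints[, 1] >= tpl$event_region[1] &
        ints[, 2] <= tpl$event_region[2]
      kind[inside] <- "event"
    }
    ci <- constitutive_introns(model0)
    if (nrow(ci) < spec$n_intron_ps)
      stop("template for ", type, " has too few constitutive introns")
    ipos <- t(vapply(seq_len(spec$n_intron_ps), function(k)
      .ps_in_region(ci[k, ]), numeric(2)))
    ints <- rbind(ints, ipos)
    kind <- c(kind, rep("intron", nrow(ipos)))
    # decoy goes into the first region, a full-width exon in every template
    first_reg <- tpl$ps_regions[1L, ]
    out <- list(isoforms = model0$isoforms, ints = ints, kind = kind,
                decoy = c(first_reg[1] + 60L, first_reg[1] + 80L))
    tpl_cache[[key]] <<- out
    out
  }
  ps_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (g in seq_len(n)) {
    tpl <- prepared(status[g], strands[g])
    off <- (g - 1L) * offset_step
    models[[g]] <- structure(
      list(gene_id = gene_ids[g], strand = strands[g], chrom = "chr1",
           isoforms = lapply(tpl$isoforms, function(m) m + off)),
      class = "gene_model")
    ints <- tpl$ints + off
    kind <- tpl$kind
    if (has_decoy[g]) {
      ints <- rbind(ints, tpl$decoy + off)
      kind <- c(kind, "decoy")
    }
    ps_rows[[g]] <- list(
      ps_id = sprintf("%s_ps%02d", gene_ids[g], seq_len(nrow(ints))),
      gene_id = rep(gene_ids[g], nrow(ints)),
      start = as.integer(ints[, 1]), end = as.integer(ints[, 2]),
      strand = rep(strands[g], nrow(ints)), kind = kind)
    truth_rows[[g]] <- c(
      gene_id = gene_ids[g], status = status[g], strand = strands[g],
      event_ps = paste(ps_rows[[g]]$ps_id[kind == "event"], collapse = ","))
  }
  cat_field <- function(f) unlist(lapply(ps_rows, `[[`, f), use.names = FALSE)
  ps <- data.frame(ps_id = cat_field("ps_id"), gene_id = cat_field("gene_id"),
                   chrom = "chr1", start = cat_field("start"),
                   end = cat_field("end"), strand = cat_field("strand"),
                   tier = "full", kind = cat_field("kind"),
                   stringsAsFactors = FALSE)
  tm <- do.call(rbind, truth_rows)
  truth <- data.frame(tm, stringsAsFactors = FALSE)
  rownames(ps) <- rownames(truth) <- NULL
  list(models = models,
       ps = ps[, c("ps_id", "gene_id", "chrom", "start", "end", "strand",
                   "tier")],
       truth = list(genes = truth,
                    ps = ps[, c("ps_id", "gene_id", "kind")]))
}

#' Simulate a signal time course with injected DE and TIV
#'
#' Baselines are drawn per gene (`N(baseline_mean, baseline_sd)`) with a
#' per-probe-set jitter (`ps_sd`); constitutive-intron and decoy probe
#' sets sit `intron_offset` log2 below. Differentially expressed genes
#' shift all true-exonic probe sets by `de_log2fc` (random sign) with a
#' ramp saturating at 60 min; TIV genes shift only their event-region
#' probe sets by `tiv_delta` (random sign) over a run of `tiv_run`
#' adjacent post-stimulus time points (uniformly placed). Replicate noise
#' is Gaussian with the intensity-dependent SD of the spec's noise curve;
#' detection p-values follow a logistic link in the true signal.
#'
#' @param gm result of [simulate_gene_models()].
#' @param spec the same [simulation_spec()].
#' @return list with `signal` (a [signal_set()]) and `truth` (the gene
#'   table extended with injected signs/runs, plus the probe-set table).
#' @export
simulate_timecourse <- function(gm, spec) {
  set.seed(spec$seed + 1L)
  tp <- spec$times; R <- spec$replicates
  samples <- data.frame(
    sample_id = as.vector(outer(seq_len(R), tp,
                                function(r, t) sprintf("t%03d_r%d", t, r))),
    time_minutes = rep(tp, each = R), replicate = rep(seq_len(R), length(tp)),
    stringsAsFactors = FALSE)
  ps <- gm$truth$ps
  genes <- gm$truth$genes
  n_ps <- nrow(ps)
  gidx <- match(ps$gene_id, genes$gene_id)

  base_gene <- stats::rnorm(nrow(genes), spec$baseline_mean, spec$baseline_sd)
  base_ps <- base_gene[gidx] + stats::rnorm(n_ps, 0, spec$ps_sd)
  low <- ps$kind %in% c("intron", "decoy")
  base_ps[low] <- base_ps[low] + spec$intron_offset

  # per-gene injected trajectories
  genes$de_sign <- ifelse(genes$status == "de",
                          sample(c(-1, 1), nrow(genes), replace = TRUE), 0)
  is_tiv <- !genes$status %in% c("none", "de")
  genes$tiv_sign <- ifelse(is_tiv, sample(c(-1, 1), nrow(genes), replace = TRUE), 0)
  n_post <- length(tp) - 1L
  genes$run_start <- ifelse(is_tiv,
                            sample.int(n_post - spec$tiv_run + 1L, nrow(genes),
                                       replace = TRUE), NA_integer_)
  genes$run_len <- ifelse(is_tiv, spec$tiv_run, NA_integer_)

  ramp <- pmin(tp / 60, 1)
  mean_mat <- matrix(base_ps, n_ps, length(tp))
  # DE: all exonic (non-decoy) probe sets of the gene
  de_ps <- genes$de_sign[gidx] != 0 & ps$kind %in% c("exon", "event")
  if (any(de_ps))
    mean_mat[de_ps, ] <- mean_mat[de_ps, ] +
      outer(genes$de_sign[gidx][de_ps] * spec$de_log2fc, ramp)
  # TIV: event probe sets over the assigned run (post-stimulus indices)
  ev_ps <- which(ps$kind == "event")
  for (i in ev_ps) {
    gi <- gidx[i]
    run <- genes$run_start[gi] + seq_len(genes$run_len[gi]) - 1L + 1L
    mean_mat[i, run] <- mean_mat[i, run] + genes$tiv_sign[gi] * spec$tiv_delta
  }

  sd_ps <- sigma_at(spec, base_ps)
  values <- matrix(NA_real_, n_ps, nrow(samples),
                   dimnames = list(ps$ps_id, samples$sample_id))
  for (k in seq_along(tp)) {
    cols <- which(samples$time_minutes == tp[k])
    values[, cols] <- mean_mat[, k] +
      matrix(stats::rnorm(n_ps * R, 0, sd_ps), n_ps, R)
  }
  detp <- stats::plogis(spec$detect_k *
    (spec$detect_mid - values +
       matrix(stats::rnorm(length(values), 0, spec$detect_jitter),
              nrow(values), ncol(values))))
  dimnames(detp) <- dimnames(values)
  sig <- signal_set(values, detp, samples)
  list(signal = sig,
       truth = list(genes = genes,
                    ps = transform(ps, baseline = base_ps)))
}

#' Simulate a scratch-assay image series
#'
#' Renders a full scene per time point: two textured cell sheets flanking a
#' vertical gap whose half-width shrinks at `speed` pixels per hour per
#' front, cut into a `tile_nrow x tile_ncol` grid of tiles.
#'
#' @param spec a [simulation_spec()].
#' @param speed closure speed (px/h per front), default
#'   `spec$closure_speed`.
#' @param seed random seed, default `spec$seed`.
#' @return list with `times_h`, `grids` (list of [tile_grid()]), `scenes`
#'   (full images), and `truth` (data frame of true gap widths).
#' @export
simulate_scratch <- function(spec, speed = spec$closure_speed,
                             seed = spec$seed) {
  H <- spec$tile_nrow * spec$tile_h
  W <- spec$tile_ncol * spec$tile_w
  cx <- (W + 1) / 2
  times <- spec$scratch_times_h
  grids <- scenes <- vector("list", length(times))
  truth <- data.frame(time_h = times, gap_width = NA_real_)
  for (k in seq_along(times)) {
    # reseed per acquisition: the texture field is static, only the fronts
    # advance (so zero closure speed yields identical images)
    set.seed(seed)
    h <- max(0, spec$gap0 / 2 - speed * times[k])
    sheet_col <- abs(seq_len(W) - cx) >= h
    sheet <- matrix(rep(sheet_col, each = H), H, W)
    texture <- gaussian_blur(matrix(stats::runif(H * W), H, W), 2)
    texture <- (texture - min(texture)) / max(1e-9, diff(range(texture)))
    img <- ifelse(sheet, spec$sheet_level + spec$texture_amp * texture, 0.04) +
      matrix(stats::rnorm(H * W, 0, spec$noise_level), H, W)
    img <- pmin(pmax(img, 0), 1)
    scenes[[k]] <- img
    tiles <- list()
    for (r in seq_len(spec$tile_nrow)) for (cc in seq_len(spec$tile_ncol)) {
      tiles[[length(tiles) + 1L]] <-
        img[((r - 1L) * spec$tile_h + 1L):(r * spec$tile_h),
            ((cc - 1L) * spec$tile_w + 1L):(cc * spec$tile_w), drop = FALSE]
    }
    grids[[k]] <- tile_grid(tiles, spec$tile_nrow, spec$tile_ncol,
                            time_h = times[k])
    truth$gap_width[k] <- 2 * h
  }
  list(times_h = times, grids = grids, scenes = scenes, truth = truth)
}

#' Simulate an siRNA screen plate
#'
#' Builds the plate map (two oligonucleotides per isoform, one gene-level
#' pool per gene, one negative-control oligo) and draws well AMD values
#' `N(amd0 * effect, amd_sd)` with `screen_replicates` replicates per
#' oligo.
#'
#' @param spec a [simulation_spec()].
#' @param effects named numeric vector of multiplicative AMD effects per
#'   oligo id (default: all 1, a null screen). Unnamed oligos keep
#'   effect 1.
#' @param seed random seed, default `spec$seed`.
#' @return list with `amd` (well AMD table), `platemap`, and `truth`
#'   (per-oligo true effect).
#' @export
simulate_screen <- function(spec, effects = NULL, seed = spec$seed) {
  set.seed(seed)
  rows <- list()
  for (g in seq_along(spec$screen_iso_counts)) {
    gid <- sprintf("G%02d", g)
    for (iso in seq_len(spec$screen_iso_counts[g])) {
      for (o in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(
          oligo_id = sprintf("%s_i%d_o%d", gid, iso, o), gene_id = gid,
          target = paste0("isoform", iso), stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      oligo_id = paste0(gid, "_pool"), gene_id = gid, target = "gene_level",
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    oligo_id = "ctrl", gene_id = "control", target = "control",
    stringsAsFactors = FALSE)
  oligos <- do.call(rbind, rows)
  nrep <- ifelse(oligos$target == "control", spec$n_control_wells,
                 spec$screen_replicates)
  platemap <- data.frame(
    well_id = sprintf("w%04d", seq_len(sum(nrep))),
    oligo_id = rep(oligos$oligo_id, nrep),
    gene_id = rep(oligos$gene_id, nrep),
    target = rep(oligos$target, nrep), stringsAsFactors = FALSE)
  eff <- stats::setNames(rep(1, nrow(oligos)), oligos$oligo_id)
  if (!is.null(effects)) eff[names(effects)] <- effects
  amd <- data.frame(
    well_id = platemap$well_id,
    amd = stats::rnorm(nrow(platemap),
                       spec$amd0 * eff[platemap$oligo_id], spec$amd_sd),
    stringsAsFactors = FALSE)
  list(amd = amd, platemap = platemap,
       truth = data.frame(oligo_id = oligos$oligo_id,
                          effect = unname(eff[oligos$oligo_id]),
                          stringsAsFactors = FALSE))
}

#' Run the full array pipeline on a signal set
#'
#' Convenience wrapper chaining annotation, presence filtering, background
#' estimation, exon refinement, noise fitting, fold changes, gene-level
#' fold changes, DE calls and TIV calls with the package defaults.
#'
#' @param sig a [signal_set()].
#' @param models named list of `gene_model` objects.
#' @param ps probe-set annotation table.
#' @param alpha FDR threshold for DE and TIV calls.
#' @param fc_min minimal linear fold change for DE calls.
#' @param min_adjacent TIV adjacency requirement.
#' @param q_int background quantile for exon refinement.
#' @return list with all intermediate results (`annot`, `presence`,
#'   `background`, `refined`, `noise`, `fc`, `gfc`, `de`, `dev`,
#'   `events`).
#' @export
tiv_pipeline <- function(sig, models, ps, alpha = 0.05, fc_min = 1.5,
                         min_adjacent = 2L, q_int = 0.95) {
  annot <- annotate_probesets(ps, models)
  pres <- presence_mask(sig)
  bg <- intron_background(sig, annot)
  ref <- refine_exons(sig, annot, bg, q_int = q_int)
  noise <- fit_noise(sig)
  fc <- fold_changes(sig, pres, noise)
  gfc <- gene_fc(fc, ref$annot)
  de <- call_de_genes(gfc, fc_min = fc_min, alpha = alpha)
  dev <- deviation_stats(fc, gfc)
  events <- call_tiv(dev, alpha = alpha, min_adjacent = min_adjacent)
  list(annot = annot, presence = pres, background = bg, refined = ref,
       noise = noise, fc = fc, gfc = gfc, de = de, dev = dev,
       events = events)
}
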