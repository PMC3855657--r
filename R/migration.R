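# Scratch-assay image quantification: tile merging, gap segmentation,
# average migration distance (AMD), and siRNA screen statistics.
#
# Images are plain numeric matrices (rows = y, cols = x, values >= 0).
# On-disk interchange uses ASCII PGM (P2), the simplest standard grayscale
# text format, so fixtures stay text-only.

.clamp_idx <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma); w <- w / sum(w)
  tmp <- matrix(0, nrow(img), ncol(img))
  for (k in -r:r) tmp <- tmp + w[k + r + 1L] * img[.clamp_idx(nrow(img), k), ,
                                                   drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (k in -r:r) out <- out + w[k + r + 1L] * tmp[, .clamp_idx(ncol(img), k),
                                                   drop = FALSE]
  out
}

# Otsu threshold over the observed intensity range (scale invariant)
otsu_threshold <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(pmax(
    as.integer((img - rng[1L]) / diff(rng) * n_bins) + 1L, 1L), n_bins),
    nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1L] + k / n_bins * diff(rng)
}

.disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

.morph <- function(mask, offsets, op) {
  acc <- NULL
  for (i in seq_len(nrow(offsets))) {
    sh <- mask[.clamp_idx(nrow(mask), offsets$dy[i]),
               .clamp_idx(ncol(mask), offsets$dx[i]), drop = FALSE]
    acc <- if (is.null(acc)) sh else op(acc, sh)
  }
  acc
}

# morphological closing (dilation then erosion) with a disk element
binary_close <- function(mask, r = 5L) {
  off <- .disk_offsets(r)
  .morph(.morph(mask, off, `|`), off, `&`)
}

#' Bundle microscopy tiles into a grid
#'
#' @param tiles list of numeric matrices in row-major order (row 1 left to
#'   right, then row 2, ...).
#' @param nrow,ncol grid shape, default 6 x 4.
#' @param time_h acquisition time in hours (metadata).
#' @return object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, nrow = 6L, ncol = 4L, time_h = NA_real_) {
  if (length(tiles) != nrow * ncol)
    stop("incomplete grid: expected ", nrow * ncol, " tiles, got ", length(tiles))
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("mismatched tile shapes")
  structure(list(tiles = tiles, nrow = nrow, ncol = ncol, time_h = time_h),
            class = "tile_grid")
}

#' Merge a tile grid into one grayscale image
#'
#' Tiles are mosaicked row-major and the result is rescaled to the unit
#' interval (`(x - min) / (max - min)`; a constant mosaic is returned
#' unchanged, clipped to `[0, 1]`).
#'
#' @param grid a [tile_grid()].
#' @return numeric matrix with values in `[0, 1]`.
#' @export
merge_tiles <- function(grid) {
  rows <- lapply(seq_len(grid$nrow), function(r) {
    do.call(cbind, grid$tiles[((r - 1L) * grid$ncol + 1L):(r * grid$ncol)])
  })
  img <- do.call(rbind, rows)
  rng <- range(img)
  if (diff(rng) == 0) return(pmin(pmax(img, 0), 1))
  (img - rng[1L]) / diff(rng)
}

#' Measure the scratch gap width of a monolayer image
#'
#' The top and bottom `crop_frac` of rows are discarded to keep only the
#' homogeneous central portion of the scratch; the image is Gaussian
#' smoothed, thresholded by Otsu's method, and the foreground (cell) mask
#' is closed with a disk of radius `close_r`. Per remaining row the gap is
#' the longest background run intersecting the central column band (middle
#' half of the image), and the reported width is the mean over rows.
#'
#' @param img numeric matrix (e.g. from [merge_tiles()]).
#' @param crop_frac fraction of rows discarded at top and bottom,
#'   default 0.15.
#' @param blur_sigma Gaussian smoothing SD in pixels, default 2.
#' @param close_r closing disk radius in pixels, default 5.
#' @return list with `width` (pixels), `closed` (no gap found), and
#'   `per_row` widths.
#' @export
segment_gap <- function(img, crop_frac = 0.15, blur_sigma = 2, close_r = 5L) {
  stopifnot(crop_frac >= 0, crop_frac < 0.5)
  H <- nrow(img); W <- ncol(img)
  drop_n <- floor(H * crop_frac)
  img <- img[(drop_n + 1L):(H - drop_n), , drop = FALSE]
  sm <- gaussian_blur(img, blur_sigma)
  fg <- sm > otsu_threshold(sm)
  if (mean(fg) < 0.05) stop("no cells detected (foreground < 5% of pixels)")
  mask <- binary_close(fg, close_r)
  band <- c(floor(W * 0.25) + 1L, ceiling(W * 0.75))
  # a genuine scratch is vertically coherent: gap columns are background in
  # most rows; random texture holes are not
  col_bg <- colMeans(!mask)
  core <- which(col_bg >= 0.5)
  core <- core[core >= band[1L] & core <= band[2L]]
  if (length(core) == 0L)
    return(list(width = 0, closed = TRUE,
                per_row = rep(0L, nrow(mask))))
  per_row <- apply(!mask, 1L, function(bg) {
    r <- rle(bg)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ok <- r$values & starts <= max(core) & ends >= min(core)
    if (!any(ok)) 0L else max(r$lengths[ok])
  })
  width <- mean(per_row)
  list(width = width, closed = width == 0, per_row = per_row)
}

#' Average migration distance from a gap-width time series
#'
#' The two wound fronts advance symmetrically, so the per-front migration
#' distance is half the gap closure relative to the initial width:
#' `AMD(t) = max(0, (width(0) - width(t)) / 2)`. The alternative
#' `fraction_closed` mode reports `(width(0) - width(t)) / width(0)`.
#'
#' @param widths named or plain numeric vector of gap widths (pixels).
#' @param times_h acquisition times in hours; must include 0.
#' @param well_id well identifier (metadata).
#' @param amd_mode `"per_front"` (default) or `"fraction_closed"`.
#' @param pixel_size optional micrometres per pixel (metadata).
#' @return object of class `well_trace` with `times_h`, `width`, `amd`.
#' @export
amd_trace <- function(widths, times_h, well_id = NA_character_,
                      amd_mode = c("per_front", "fraction_closed"),
                      pixel_size = NULL) {
  amd_mode <- match.arg(amd_mode)
  stopifnot(length(widths) == length(times_h))
  o <- order(times_h)
  times_h <- times_h[o]; widths <- widths[o]
  if (times_h[1L] != 0) stop("missing t = 0 acquisition")
  if (widths[1L] <= 0) stop("initial gap width must be positive")
  amd <- if (amd_mode == "per_front") pmax(0, (widths[1L] - widths) / 2)
         else pmax(0, (widths[1L] - widths) / widths[1L])
  structure(list(well_id = well_id, times_h = times_h, width = widths,
                 amd = amd, amd_mode = amd_mode, pixel_size = pixel_size),
            class = "well_trace")
}

#' siRNA screen statistics on well-level AMD values
#'
#' Each well's AMD is normalized to the mean AMD of the negative-control
#' wells (relative AMD, control = 1). Per oligonucleotide, the mean and
#' standard error over replicates are reported and a two-sided Welch t-test
#' compares its wells with the control wells; Benjamini-Hochberg FDR is
#' applied across all non-control oligos and an oligo is significant if
#' its q-value is below `alpha_q`.
#'
#' @param amd data frame with columns `well_id`, `amd`.
#' @param platemap data frame with columns `well_id`, `oligo_id`,
#'   `gene_id`, `target` (`"isoform<k>"`, `"gene_level"` or `"control"`).
#' @param alpha_q FDR threshold, default 0.01.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @return data frame per oligo: `oligo_id`, `gene_id`, `target`, `n`,
#'   `mean_rel_amd`, `se`, `p`, `q`, `significant`, `direction`.
#' @export
screen_statistics <- function(amd, platemap, alpha_q = 0.01,
                              test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  df <- merge(amd, platemap, by = "well_id")
  ctrl <- df$amd[df$target == "control"]
  if (length(ctrl) == 0L) stop("no negative-control wells in plate map")
  df$rel <- df$amd / mean(ctrl)
  ctrl_rel <- df$rel[df$target == "control"]
  oligos <- unique(df$oligo_id[df$target != "control"])
  res <- lapply(oligos, function(o) {
    sub <- df[df$oligo_id == o, , drop = FALSE]
    x <- sub$rel
    if (length(x) < 2L) stop("oligo ", o, " has < 2 replicates")
    if (test == "welch") {
      p <- .welch_p(x, ctrl_rel)
    } else {
      p <- stats::wilcox.test(x, ctrl_rel, exact = FALSE)$p.value
    }
    data.frame(oligo_id = o, gene_id = sub$gene_id[1L],
               target = sub$target[1L], n = length(x),
               mean_rel_amd = mean(x),
               se = stats::sd(x) / sqrt(length(x)),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha_q
  res$direction <- ifelse(res$significant,
                          ifelse(res$mean_rel_amd < 1, "down", "up"), "none")
  rownames(res) <- NULL
  res
}

.welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  2 * stats::pt(-abs(tt), df)
}

#' Call isoform-specific screen hits
#'
#' An isoform is an isoform-specific hit in a direction when (i) both of
#' its oligonucleotides are significant in that direction, (ii) no
#' alternate isoform of the gene has both its oligonucleotides significant
#' in that direction, and (iii) the gene-level pool is not significant in
#' that direction. An isoform with fewer than two scored oligonucleotides
#' is unevaluable.
#'
#' @param results data frame from [screen_statistics()].
#' @param min_oligos oligos required per isoform, default 2.
#' @return data frame per (gene, isoform): `evaluable`, `hit`,
#'   `direction`.
#' @export
isoform_hit_call <- function(results, min_oligos = 2L) {
  iso <- results[grepl("^isoform", results$target), , drop = FALSE]
  out <- list()
  for (g in unique(iso$gene_id)) {
    sub <- iso[iso$gene_id == g, , drop = FALSE]
    gl <- results[results$gene_id == g & results$target == "gene_level", ,
                  drop = FALSE]
    consistent_dir <- function(t, d) {
      o <- sub[sub$target == t, , drop = FALSE]
      nrow(o) >= min_oligos && all(o$significant & o$direction == d)
    }
    for (t in unique(sub$target)) {
      o <- sub[sub$target == t, , drop = FALSE]
      if (nrow(o) < min_oligos) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, isoform = t, evaluable = FALSE, hit = FALSE,
          direction = NA_character_, stringsAsFactors = FALSE)
        next
      }
      hit <- FALSE; dir <- NA_character_
      for (d in c("down", "up")) {
        if (!consistent_dir(t, d)) next
        others <- setdiff(unique(sub$target), t)
        alt_block <- any(vapply(others, consistent_dir, logical(1), d = d))
        gl_block <- nrow(gl) > 0L &&
          any(gl$significant & gl$direction == d)
        if (!alt_block && !gl_block) { hit <- TRUE; dir <- d }
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, isoform = t, evaluable = TRUE, hit = hit,
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$isoform), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read / write ASCII PGM (P2) grayscale images
#'
#' Values are scaled to the PGM maxval on write and back to `[0, 1]` on
#' read.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param path file path.
#' @param maxval PGM maximum gray value, default 255.
#' @return `read_pgm`: numeric matrix in `[0, 1]`; `write_pgm`: `path`.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  v <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1L] != "P2") stop("not an ASCII PGM (P2) file")
  hdr <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  maxval <- as.integer(lines[3L])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals, nrow = hdr[2L], ncol = hdr[1L], byrow = TRUE) / maxval
}
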