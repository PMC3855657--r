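test_that("merge_tiles mosaics row-major and rescales", {
  # 2x2 constant tiles -> constant mosaic of doubled linear size
  tiles <- replicate(4, matrix(0.5, 10, 10), simplify = FALSE)
  g <- tile_grid(tiles, 2, 2)
  m <- merge_tiles(g)
  expect_equal(dim(m), c(20L, 20L))
  expect_true(all(m == 0.5))
  # single tile -> identity up to rescale
  t1 <- matrix(seq(0, 1, length.out = 25), 5, 5)
  m1 <- merge_tiles(tile_grid(list(t1 * 7 + 2), 1, 1))
  expect_equal(m1, t1)
  # tile order is row-major
  tiles2 <- list(matrix(0, 2, 2), matrix(1, 2, 2),
                 matrix(2, 2, 2), matrix(3, 2, 2))
  m2 <- merge_tiles(tile_grid(tiles2, 2, 2))
  expect_equal(m2[1, 3], 1 / 3)  # tile 2 top-right
  expect_equal(m2[3, 1], 2 / 3)  # tile 3 bottom-left
  expect_error(tile_grid(tiles2[1:3], 2, 2), "incomplete")
  expect_error(tile_grid(c(tiles2[1:3], list(matrix(0, 3, 2))), 2, 2),
               "mismatched")
})

test_that("mosaic of generated tiles equals the rescaled full scene", {
  spec <- simulation_spec(seed = 81)
  sc <- simulate_scratch(spec)
  scene <- sc$scenes[[1]]
  scene_rs <- (scene - min(scene)) / diff(range(scene))
  expect_equal(merge_tiles(sc$grids[[1]]), scene_rs, tolerance = 1e-12)
})

test_that("segment_gap recovers known gap widths within 2% or 6 px", {
  spec <- simulation_spec(seed = 83)
  sc <- simulate_scratch(spec)
  for (k in seq_along(sc$times_h)) {
    est <- segment_gap(merge_tiles(sc$grids[[k]]))
    truth <- sc$truth$gap_width[k]
    expect_lt(abs(est$width - truth), max(0.02 * truth, 6),
              label = paste("time", sc$times_h[k]))
  }
})

test_that("segment_gap handles closed monolayers and detects missing cells", {
  spec <- simulation_spec(seed = 85)
  sc <- simulate_scratch(spec, speed = 50)  # closed well before 20 h
  est <- segment_gap(merge_tiles(sc$grids[[length(sc$grids)]]))
  expect_true(est$closed)
  expect_equal(est$width, 0)
  # mostly dark field with one small bright patch: foreground < 5%
  set.seed(1)
  dark <- matrix(abs(rnorm(200 * 100, 0, 0.02)), 200, 100)
  dark[60:71, 40:51] <- 1
  expect_error(segment_gap(dark), "no cells")
})

test_that("segment_gap is invariant to intensity scaling and vertical flips", {
  spec <- simulation_spec(seed = 87)
  sc <- simulate_scratch(spec)
  img <- merge_tiles(sc$grids[[2]])
  base <- segment_gap(img)$width
  expect_equal(segment_gap(img * 3.7)$width, base)
  expect_equal(segment_gap(img[nrow(img):1, ])$width, base)
})

test_that("cropping suppresses spurious holes near the image border", {
  spec <- simulation_spec(seed = 89)
  sc <- simulate_scratch(spec)
  img <- merge_tiles(sc$grids[[1]])
  truth <- sc$truth$gap_width[1]
  # punch a dark hole through the top band of the left sheet
  img[1:30, 40:120] <- 0.02
  with_crop <- segment_gap(img, crop_frac = 0.15)$width
  no_crop <- segment_gap(img, crop_frac = 0)$width
  expect_lt(abs(with_crop - truth), abs(no_crop - truth))
})

test_that("amd_trace implements the per-front convention", {
  tr <- amd_trace(c(400, 100), c(0, 20))
  expect_equal(unname(tr$amd), c(0, 150))  # (400-100)/2
  tr2 <- amd_trace(c(400, 400, 400), c(0, 10, 20))
  expect_equal(unname(tr2$amd), c(0, 0, 0))
  # widths below the initial value floor at 0, never negative
  tr3 <- amd_trace(c(100, 150), c(0, 20))
  expect_equal(unname(tr3$amd), c(0, 0))
  expect_error(amd_trace(c(400, 100), c(10, 20)), "t = 0")
  expect_error(amd_trace(c(0, 0), c(0, 20)), "positive")
  # fraction-closed alternative
  tr4 <- amd_trace(c(400, 100), c(0, 20), amd_mode = "fraction_closed")
  expect_equal(unname(tr4$amd), c(0, 0.75))
})

test_that("AMD from segmented synthetic series tracks the true closure speed", {
  spec <- simulation_spec(seed = 91)
  sc <- simulate_scratch(spec)  # 3 px/h per front
  widths <- vapply(sc$grids, function(g) segment_gap(merge_tiles(g))$width,
                   numeric(1))
  tr <- amd_trace(widths, sc$times_h)
  expect_true(all(diff(tr$amd) >= -1e-9))  # monotone on a closing series
  slope <- coef(lm(tr$amd ~ tr$times_h))[2]
  expect_lt(abs(slope - spec$closure_speed) / spec$closure_speed, 0.05)
})

test_that("screen_statistics normalizes to controls and tests vs control wells", {
  spec <- simulation_spec(seed = 93)
  sim <- simulate_screen(spec)  # null screen
  res <- screen_statistics(sim$amd, sim$platemap)
  expect_equal(nrow(res), 189L)  # 154 isoform oligos + 35 pools
  expect_lt(abs(mean(res$mean_rel_amd) - 1), 0.05)
  expect_true(all(res$se >= 0))
  # control relative AMD averages 1 by construction
  df <- merge(sim$amd, sim$platemap, by = "well_id")
  ctrl <- df$amd[df$target == "control"]
  expect_equal(mean(ctrl / mean(ctrl)), 1)
  # a strong effect is detected
  eff <- c(G01_i2_o1 = 0.5, G01_i2_o2 = 0.5)
  sim2 <- simulate_screen(spec, effects = eff, seed = 95)
  res2 <- screen_statistics(sim2$amd, sim2$platemap)
  expect_true(all(res2$significant[res2$oligo_id %in% names(eff)]))
  expect_true(all(res2$direction[res2$oligo_id %in% names(eff)] == "down"))
  expect_error(screen_statistics(sim$amd,
                                 sim$platemap[sim$platemap$target != "control", ]),
               "control")
})

test_that("isoform_hit_call follows the consistency rule (PTHLH-like)", {
  spec <- simulation_spec(seed = 97)
  eff <- c(G01_i2_o1 = 0.5, G01_i2_o2 = 0.5)
  sim <- simulate_screen(spec, effects = eff)
  res <- screen_statistics(sim$amd, sim$platemap)
  hits <- isoform_hit_call(res)
  flagged <- hits[hits$hit, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$gene_id, "G01")
  expect_equal(flagged$isoform, "isoform2")
  expect_equal(flagged$direction, "down")
  # one of two oligos significant -> no hit
  sim2 <- simulate_screen(spec, effects = c(G02_i1_o1 = 0.5), seed = 99)
  res2 <- screen_statistics(sim2$amd, sim2$platemap)
  h2 <- isoform_hit_call(res2)
  expect_false(any(h2$hit[h2$gene_id == "G02"]))
})

test_that("isoform_hit_call agrees with the enumeration oracle on all patterns", {
  states <- c("down", "up", "ns")
  grid <- expand.grid(i1o1 = states, i1o2 = states, i2o1 = states,
                      i2o2 = states, pool = states,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    st <- unlist(grid[r, ])
    res <- data.frame(
      oligo_id = names(st),
      gene_id = "G",
      target = c("isoform1", "isoform1", "isoform2", "isoform2",
                 "gene_level"),
      n = 11L, mean_rel_amd = ifelse(st == "down", 0.5,
                                     ifelse(st == "up", 1.5, 1)),
      se = 0.05, p = 0.5, q = 0.5,
      significant = st != "ns",
      direction = ifelse(st == "ns", "none", st),
      stringsAsFactors = FALSE)
    got <- isoform_hit_call(res)
    # independent truth-table evaluation
    both <- function(o1, o2, d) st[o1] == d && st[o2] == d
    want_hit <- function(iso) {
      os <- if (iso == "isoform1") c("i1o1", "i1o2") else c("i2o1", "i2o2")
      alt <- if (iso == "isoform1") c("i2o1", "i2o2") else c("i1o1", "i1o2")
      any(vapply(c("down", "up"), function(d)
        both(os[1], os[2], d) && !both(alt[1], alt[2], d) &&
          st["pool"] != d, logical(1)))
    }
    for (iso in c("isoform1", "isoform2")) {
      expect_equal(got$hit[got$isoform == iso], want_hit(iso),
                   info = paste(r, iso))
    }
  }
})

test_that("PGM image round-trip preserves the image", {
  set.seed(101)
  img <- matrix(runif(40 * 30), 40, 30)
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  back <- read_pgm(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})
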