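# helpers to build tiny fc_table / gene_fc / deviation_stats objects by hand
make_fc_table <- function(fc, var, times) {
  structure(list(fc = fc, var = var, times = times, R = 3L), class = "fc_table")
}

test_that("fold_changes computes mean differences with presence masking", {
  times <- c(0, 60)
  mm <- matrix(c(5, 6), 1, 2, dimnames = list("p1", NULL))
  sig <- make_signal_set(mm, times, R = 3, sd = 0)
  nm <- flat_noise_model(0.3)
  fc <- fold_changes(sig, presence_mask(sig), nm)
  expect_equal(unname(fc$fc["p1", "60"]), 1.0)   # (5,5,5)->(6,6,6)
  expect_equal(unname(fc$fc["p1", "0"]), 0.0)    # reference column
  expect_equal(unname(fc$var["p1", "60"]), 2 * 0.09 / 3)
  # brute-force elementwise oracle on random data
  set.seed(51)
  times <- c(0, 20, 40, 60)
  mm2 <- matrix(runif(50 * 4, 5, 9), 50, 4,
                dimnames = list(sprintf("p%02d", 1:50), NULL))
  sig2 <- make_signal_set(mm2, times, R = 3, sd = 0.3)
  fc2 <- fold_changes(sig2, presence_mask(sig2), nm)
  for (k in seq_along(times)) {
    ids <- sig2$samples$sample_id[sig2$samples$time_minutes == times[k]]
    ids0 <- sig2$samples$sample_id[sig2$samples$time_minutes == 0]
    want <- rowMeans(sig2$values[, ids]) - rowMeans(sig2$values[, ids0])
    expect_equal(unname(fc2$fc[, k]), unname(want))
  }
  # absent at t=0 -> fully masked row
  sig3 <- make_signal_set(mm, times = c(0, 60), R = 3, sd = 0)
  sig3$detection_p[1, 1:3] <- 0.5
  expect_message(fc3 <- fold_changes(sig3, presence_mask(sig3), nm), "masked")
  expect_true(all(is.na(fc3$fc)))
})

test_that("gene_fc takes medians with the even-count convention", {
  times <- c(0, 60)
  fc <- matrix(c(0, 0, 0, 0.5, 0.5, 2.0), 3, 2,
               dimnames = list(c("a", "b", "c"), c("0", "60")))
  ft <- make_fc_table(fc, fc * 0 + 0.01, times)
  annot <- data.frame(ps_id = c("a", "b", "c"), gene_id = "g1",
                      refined = "true_exon")
  g <- gene_fc(ft, annot, min_ps = 3)
  expect_equal(unname(g$fc["g1", "60"]), 0.5)
  # even count: median of {0, 1} = 0.5
  fc2 <- matrix(c(0, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("0", "60")))
  g2 <- gene_fc(make_fc_table(fc2, fc2 * 0 + 0.01, times),
                annot[1:2, ], min_ps = 2)
  expect_equal(unname(g2$fc["g1", "60"]), 0.5)
  # fewer contributing PS than min_ps -> masked
  g3 <- gene_fc(make_fc_table(fc2, fc2 * 0 + 0.01, times), annot[1:2, ])
  expect_true(is.na(g3$fc["g1", "60"]))
  # sort-based brute-force median on random tables
  set.seed(53)
  n_genes <- 60
  ann <- data.frame(ps_id = sprintf("p%03d", 1:(n_genes * 5)),
                    gene_id = rep(sprintf("g%03d", 1:n_genes), each = 5),
                    refined = "true_exon")
  fcm <- matrix(rnorm(n_genes * 5 * 3), n_genes * 5, 3,
                dimnames = list(ann$ps_id, c("0", "20", "40")))
  fcm[, 1] <- 0
  gg <- gene_fc(make_fc_table(fcm, fcm * 0 + 0.01, c(0, 20, 40)), ann)
  for (g in sample(sprintf("g%03d", 1:n_genes), 10)) {
    rows <- ann$ps_id[ann$gene_id == g]
    for (k in 2:3) {
      v <- sort(fcm[rows, k])
      want <- (v[3] + v[3]) / 2  # 5 values: middle one
      expect_equal(unname(gg$fc[g, k]), unname(v[3]))
    }
  }
})

test_that("call_de_genes applies both the FDR and fold-change thresholds", {
  times <- c(0, 20, 40, 60)
  genes <- sprintf("g%02d", 1:40)
  fc <- matrix(0, 40, 4, dimnames = list(genes, as.character(times)))
  va <- matrix(1.57 * 0.04 / 8, 40, 4, dimnames = dimnames(fc))
  fc["g01", 2:4] <- 1.0    # linear 2.0, huge z -> called
  fc["g02", 2:4] <- 0.379  # linear 1.3, significant but below fc_min
  gfc <- structure(list(fc = fc, var = va,
                        n = matrix(8L, 40, 4, dimnames = dimnames(fc)),
                        times = times, ps_gene = character(0)),
                   class = "gene_fc")
  de <- call_de_genes(gfc)
  calls <- de$calls
  expect_true(calls$de[calls$gene_id == "g01"])
  expect_false(calls$de[calls$gene_id == "g02"])  # fc_min rule dominates
  expect_equal(de$table$direction[de$table$gene_id == "g01" &
                                    de$table$time == 20], "up")
  # a gene may be up early and down late
  fc["g03", 2] <- 1.0; fc["g03", 4] <- -1.0
  gfc$fc <- fc
  de2 <- call_de_genes(gfc)
  dirs <- de2$table$direction[de2$table$gene_id == "g03"]
  expect_setequal(unique(dirs), c("up", "down", "none"))
})

test_that("deviation_stats computes delta, z and p per contract", {
  times <- c(0, 60)
  fcm <- matrix(c(0, 0, 0, 2.0, 1.0, 1.0), 3, 2,
                dimnames = list(c("a", "b", "c"), c("0", "60")))
  vam <- fcm * 0 + 0.05
  ft <- make_fc_table(fcm, vam, times)
  gfc <- structure(list(
    fc = matrix(c(0, 1.0), 1, 2, dimnames = list("g1", c("0", "60"))),
    var = matrix(0.0125, 1, 2, dimnames = list("g1", c("0", "60"))),
    n = matrix(3L, 1, 2), times = times,
    ps_gene = c(a = "g1", b = "g1", c = "g1")), class = "gene_fc")
  dev <- deviation_stats(ft, gfc)
  expect_equal(unname(dev$delta["a", "60"]), 1.0)
  expect_equal(unname(dev$delta["b", "60"]), 0.0)
  expect_equal(unname(dev$p["b", "60"]), 1.0)  # PS equal to gene FC
  expect_equal(unname(dev$z["a", "60"]), 1.0 / sqrt(0.05 + 0.0125))
  # z = 4 gives the textbook two-sided normal p
  expect_equal(2 * pnorm(-4), 6.334e-05, tolerance = 1e-3)
})

test_that("call_tiv enforces adjacency, sign consistency and merging", {
  times <- c(0, 20, 40, 60, 120, 240, 480)
  post <- as.character(times[-1])
  mk_dev <- function(p, delta, gene = c(a = "g1", b = "g2")) {
    structure(list(delta = delta, z = delta, p = p, gene = gene,
                   times = times[-1]), class = "deviation_stats")
  }
  base_p <- matrix(1, 2, 6, dimnames = list(c("a", "b"), post))
  base_d <- matrix(0.01, 2, 6, dimnames = list(c("a", "b"), post))
  # flagged at consecutive 60,120 -> one event; 20,240 alone -> none
  p1 <- base_p; p1["a", c("60", "120")] <- 1e-10
  p1["b", c("20", "240")] <- 1e-10
  d1 <- base_d; d1["a", ] <- 1; d1["b", ] <- 1
  ev <- call_tiv(mk_dev(p1, d1))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene_id, "g1")
  expect_equal(ev$time_start, 60)
  expect_equal(ev$time_end, 120)
  expect_false(ev$switch_like)
  # sign flip inside a run splits it
  p2 <- base_p; p2["a", c("40", "60", "120")] <- 1e-10
  d2 <- base_d; d2["a", c("40", "60")] <- 1; d2["a", "120"] <- -1
  ev2 <- call_tiv(mk_dev(p2, d2))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$run_len, 2L)
  # same gene, same sign, overlapping runs merge across probe sets
  p3 <- base_p; p3["a", c("40", "60")] <- 1e-10; p3["b", c("60", "120")] <- 1e-10
  d3 <- base_d; d3[] <- 1
  ev3 <- call_tiv(mk_dev(p3, d3, gene = c(a = "g1", b = "g1")))
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$ps_ids, "a,b")
  expect_equal(ev3$run_len, 3L)
  expect_true(ev3$switch_like)
  # last time point alone can never seed an event
  p4 <- base_p; p4["a", "480"] <- 1e-10
  expect_equal(nrow(call_tiv(mk_dev(p4, d1))), 0L)
})

test_that("switch_like_filter is a pure run-length filter", {
  ev <- data.frame(gene_id = c("a", "b", "c"), run_len = c(2L, 3L, 5L))
  expect_equal(switch_like_filter(ev)$gene_id, c("b", "c"))
  set.seed(55)
  ev2 <- data.frame(gene_id = sprintf("g%02d", 1:50),
                    run_len = sample(1:6, 50, replace = TRUE))
  expect_equal(switch_like_filter(ev2, 3)$gene_id,
               ev2$gene_id[ev2$run_len >= 3])  # brute-force filter
})

test_that("adding a gene-wide constant shifts gene FC but not deviations", {
  spec <- simulation_spec(seed = 61, n_genes = 40)
  gm <- simulate_gene_models(spec)
  tc <- simulate_timecourse(gm, spec)
  res <- tiv_pipeline(tc$signal, gm$models, gm$ps)
  g <- res$gfc$ps_gene[1]
  ps_of_g <- names(res$gfc$ps_gene)[res$gfc$ps_gene == g]
  sig2 <- tc$signal
  t_cols <- sig2$samples$sample_id[sig2$samples$time_minutes == 120]
  sig2$values[rownames(sig2$values) %in% gm$ps$ps_id[gm$ps$gene_id == g],
              t_cols] <-
    sig2$values[rownames(sig2$values) %in% gm$ps$ps_id[gm$ps$gene_id == g],
                t_cols] + 2
  res2 <- tiv_pipeline(sig2, gm$models, gm$ps)
  expect_equal(unname(res2$gfc$fc[g, "120"] - res$gfc$fc[g, "120"]), 2,
               tolerance = 1e-9)
  expect_equal(res2$dev$delta[ps_of_g, "120"], res$dev$delta[ps_of_g, "120"],
               tolerance = 1e-9)
})

test_that("call_tiv is invariant to gene input order", {
  spec <- simulation_spec(seed = 63, n_genes = 150)
  gm <- simulate_gene_models(spec)
  tc <- simulate_timecourse(gm, spec)
  res <- tiv_pipeline(tc$signal, gm$models, gm$ps)
  perm <- sample(nrow(tc$signal$values))
  sigp <- signal_set(tc$signal$values[perm, ], tc$signal$detection_p[perm, ],
                     tc$signal$samples)
  resp <- tiv_pipeline(sigp, gm$models, gm$ps)
  expect_equal(res$events, resp$events)
})
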