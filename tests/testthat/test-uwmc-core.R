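make_slab_mask <- function() {
  # 1 mm voxels, one lesion slab at voxel x = 10
  dat <- array(FALSE, c(21, 5, 5))
  dat[11, , ] <- TRUE
  binary_mask(dat, simple_affine())
}

test_that("passes_through detects slab crossings without a vertex inside", {
  wmh <- make_slab_mask()
  miss <- rbind(c(0, 2, 2), c(5, 2, 2))
  expect_false(passes_through(miss, wmh))
  vertex_in <- rbind(c(0, 2, 2), c(10, 2, 2))
  expect_true(passes_through(vertex_in, wmh))
  # vertices 10 mm apart straddling the slab, no vertex inside it
  straddle <- rbind(c(5, 2, 2), c(15, 2, 2))
  expect_true(passes_through(straddle, wmh))
  expect_identical(passes_through(straddle, wmh), passes_oracle(straddle, wmh))
})

test_that("passes_through equals the dense-sampling oracle on random streamlines", {
  set.seed(21)
  dat <- array(runif(20^3) < 0.02, c(20, 20, 20))
  wmh <- binary_mask(dat, simple_affine())
  disagreements <- 0L
  for (i in 1:200) {
    pts <- cbind(runif(4, -2, 21), runif(4, -2, 21), runif(4, -2, 21))
    if (passes_through(pts, wmh) != passes_oracle(pts, wmh, step = 0.01))
      disagreements <- disagreements + 1L
  }
  expect_equal(disagreements, 0L)
})

test_that("endpoint labeling is exact at d = 0 and majority-votes under dilation", {
  tab <- data.frame(id = c(3L, 9L), name = c("ra", "rb"),
                    lobe = "frontal", hemisphere = "L",
                    in_abeta_set = FALSE, in_tau_set = FALSE)
  dat <- array(0L, c(10, 5, 5))
  dat[1:3, , ] <- 3L
  dat[8:10, , ] <- 9L
  dat[4, , ] <- 0L
  labels <- label_volume(dat, simple_affine(), tab)
  s <- rbind(c(1, 2, 2), c(9, 2, 2))
  expect_equal(endpoint_labels(s, labels), c(3L, 9L))
  # unlabeled endpoint at d = 0
  s2 <- rbind(c(3, 2, 2), c(9, 2, 2))
  expect_true(is.na(endpoint_labels(s2, labels)[1]))
  # one voxel outside region 3: all nonzero neighbours within radius 1 are 3
  got <- endpoint_labels(s2, labels, intersection_config(endpoint_dilation = 1))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- sweep(off, 2, c(3, 2, 2), "+") + 1          # 1-based for direct indexing
  vals <- apply(nb, 1, function(v) dat[v[1], v[2], v[3]])
  expect_equal(got[1], as.integer(names(which.max(table(vals[vals > 0])))))
  expect_equal(got[1], 3L)
})

test_that("the worked four-streamline example yields counts (4, 2) and UWMC 0.5", {
  ph <- phantom_figure1c(seed = 1)
  counts <- count_connections(ph$streamlines, ph$labels, ph$wmh)
  expect_equal(nrow(counts), 1)
  expect_equal(counts$total, 4L)
  expect_equal(counts$unhealthy, 2L)
  mat <- pairwise_uwmc(counts)
  expect_equal(mat$uwmc, 0.5)
  expect_equal(global_uwmc(counts), 0.5)

  empty <- count_connections(streamline_set(list()), ph$labels, ph$wmh)
  expect_equal(nrow(empty), 0)
  expect_error(global_uwmc(empty), "empty")
})

test_that("multi-bundle phantom counts match planted ground truth", {
  ph <- phantom_multibundle(targets = c(0.3, 0, 1), sizes = c(10L, 6L, 8L), seed = 4)
  counts <- count_connections(ph$streamlines, ph$labels, ph$wmh)
  merged <- merge(as.data.frame(counts), as.data.frame(ph$truth), by = c("a", "b"))
  expect_equal(nrow(merged), 3)
  expect_equal(merged$total.x, merged$total.y)
  expect_equal(merged$unhealthy.x, merged$unhealthy.y)
  # independent accumulation over raw streamlines for the global ratio
  crossing <- vapply(ph$streamlines$streamlines,
                     function(s) passes_oracle(s, ph$wmh, step = 0.05), logical(1))
  expect_equal(global_uwmc(counts), sum(crossing) / length(crossing))
})

test_that("pairwise UWMC handles zero counts and flags empty denominators", {
  counts <- tibble::tibble(a = c(1L, 1L, 2L), b = c(2L, 3L, 3L),
                           total = c(4L, 7L, 0L), unhealthy = c(2L, 0L, 0L))
  mat <- pairwise_uwmc(counts)
  expect_equal(mat$uwmc, c(0.5, 0, 0))
  expect_identical(mat$zero_denominator, c(FALSE, FALSE, TRUE))
})

test_that("lobar UWMC is the ratio of sums within each lobe", {
  tab <- data.frame(id = 1:3, name = c("f1", "f2", "p1"),
                    lobe = c("frontal", "frontal", "parietal"), hemisphere = "L",
                    in_abeta_set = FALSE, in_tau_set = FALSE)
  dat <- array(0L, c(3, 1, 1)); dat[] <- 1:3
  labels <- label_volume(dat, simple_affine(), tab)
  counts <- tibble::tibble(a = c(1L, 1L), b = c(2L, 3L),
                           total = c(4L, 6L), unhealthy = c(2L, 6L))
  lob <- lobar_uwmc(counts, labels)
  expect_equal(lob$uwmc[lob$lobe == "frontal"], 2 / 4)
  # no within-parietal pair: flagged zero
  expect_true(lob$zero_denominator[lob$lobe == "parietal"])

  counts2 <- tibble::tibble(a = 1L, b = 2L, total = c(4L), unhealthy = c(2L))
  counts2 <- rbind(counts2, tibble::tibble(a = 1L, b = 2L, total = 6L, unhealthy = 0L))
  # two entries same lobe: ratio of sums 2/10, not mean of ratios 0.25
  lob2 <- lobar_uwmc(counts2, labels)
  expect_equal(lob2$uwmc[lob2$lobe == "frontal"], 0.2)
})

test_that("a lesion-free phantom yields zero UWMC everywhere and a full mask yields one", {
  ph <- phantom_multibundle(targets = c(0, 0, 0), seed = 5)
  counts <- count_connections(ph$streamlines, ph$labels, ph$wmh)
  expect_true(all(counts$unhealthy == 0L))
  expect_equal(global_uwmc(counts), 0)

  full <- binary_mask(array(TRUE, dim(ph$wmh$data)), ph$wmh$affine)
  counts_full <- count_connections(ph$streamlines, ph$labels, full)
  expect_true(all(counts_full$unhealthy == counts_full$total))
  expect_equal(global_uwmc(counts_full), 1)
})

test_that("counts are invariant to streamline reversal and rigid motion", {
  ph <- phantom_multibundle(seed = 6)
  counts <- count_connections(ph$streamlines, ph$labels, ph$wmh)

  rev_set <- streamline_set(lapply(ph$streamlines$streamlines,
                                   function(p) p[rev(seq_len(nrow(p))), ]))
  expect_equal(as.data.frame(count_connections(rev_set, ph$labels, ph$wmh)),
               as.data.frame(counts))

  # rigid transform applied to streamlines and composed into every affine
  th <- 0.35
  R <- rbind(c(cos(th), -sin(th), 0, 3),
             c(sin(th),  cos(th), 0, -7),
             c(0, 0, 1, 12),
             c(0, 0, 0, 1))
  mv <- function(v) { v$affine <- R %*% v$affine; v }
  moved <- streamline_set(lapply(ph$streamlines$streamlines, function(p) {
    w <- cbind(p, 1) %*% t(R); w[, 1:3]
  }))
  counts_mv <- count_connections(moved, mv(ph$labels), mv(ph$wmh))
  expect_equal(as.data.frame(counts_mv), as.data.frame(counts))
})

test_that("adding streamlines moves a pair's UWMC monotonically", {
  ph <- phantom_figure1c(seed = 8)
  base <- count_connections(ph$streamlines, ph$labels, ph$wmh)
  u0 <- pairwise_uwmc(base)$uwmc
  # duplicate a non-crossing streamline: UWMC must not increase
  crossing <- vapply(ph$streamlines$streamlines,
                     function(s) passes_through(s, ph$wmh), logical(1))
  plus_clean <- streamline_set(c(ph$streamlines$streamlines,
                                 ph$streamlines$streamlines[!crossing][1]))
  u1 <- pairwise_uwmc(count_connections(plus_clean, ph$labels, ph$wmh))$uwmc
  expect_lte(u1, u0)
  plus_cross <- streamline_set(c(ph$streamlines$streamlines,
                                 ph$streamlines$streamlines[crossing][1]))
  u2 <- pairwise_uwmc(count_connections(plus_cross, ph$labels, ph$wmh))$uwmc
  expect_gte(u2, u0)
})

test_that("global UWMC equals the lobar value when one lobe holds every region", {
  ph <- phantom_figure1c(seed = 9)    # both regions frontal
  counts <- count_connections(ph$streamlines, ph$labels, ph$wmh)
  lob <- lobar_uwmc(counts, ph$labels)
  expect_equal(lob$uwmc[lob$lobe == "frontal"], global_uwmc(counts))
})

test_that("pathology subsets enumerate all flagged pairs, including unobserved ones", {
  tab <- default_label_table()
  expect_equal(sum(tab$in_abeta_set), 42)
  expect_equal(sum(tab$in_tau_set), 12)
  dat <- array(0L, c(2, 2, 2))
  dat[1, 1, 1] <- tab$id[1]
  labels <- label_volume(dat, simple_affine(), tab)
  mat <- pairwise_uwmc(tibble::tibble(a = integer(0), b = integer(0),
                                      total = integer(0), unhealthy = integer(0)))
  tau_pairs <- pathology_subset(mat, labels, "tau")
  expect_equal(nrow(tau_pairs), choose(12, 2))   # 66 candidate pairs
  expect_true(all(tau_pairs$zero_denominator))
  abeta_pairs <- pathology_subset(mat, labels, "abeta")
  expect_equal(nrow(abeta_pairs), choose(42, 2)) # 861 candidate pairs
  expect_true(all(tau_pairs$a < tau_pairs$b))

  tab2 <- tab; tab2$in_tau_set <- FALSE
  expect_error(pathology_subset(mat, label_volume(dat, simple_affine(), tab2), "tau"),
               "fewer than 2")
})
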