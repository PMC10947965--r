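# Shared fixtures and independent oracles, built in code at test time.

# a small grid with an identity-ish affine and optional translation
simple_affine <- function(voxel_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  a <- diag(c(voxel_mm, 1))
  a[1:3, 4] <- origin
  a
}

# brute-force BH step-up straight from the definition
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  if (!m) return(character(0))
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0L, which(ps <= seq_len(m) * q / m)))
  if (k == 0L) character(0) else names(p)[ord[seq_len(k)]]
}

# dense-sampling intersection oracle at a fixed fine step (mm)
passes_oracle <- function(streamline, wmh, step = 0.01) {
  n <- nrow(streamline)
  seg <- streamline[-1, , drop = FALSE] - streamline[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  k <- pmax(1L, ceiling(len / step))
  idx <- rep.int(seq_len(n - 1L), k)
  tt <- sequence(k) / rep.int(k, k)
  pts <- rbind(streamline[1, , drop = FALSE],
               streamline[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * tt)
  v <- round(cbind(pts, 1) %*% t(solve(wmh$affine)))[, 1:3, drop = FALSE]
  dm <- dim(wmh$data)
  ok <- v[, 1] >= 0 & v[, 1] < dm[1] & v[, 2] >= 0 & v[, 2] < dm[2] &
    v[, 3] >= 0 & v[, 3] < dm[3]
  if (!any(ok)) return(FALSE)
  any(wmh$data[v[ok, 1] + dm[1] * (v[ok, 2] + dm[2] * v[ok, 3]) + 1])
}

# hand-rolled Dice coefficient between two masks
dice_of <- function(a, b) 2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))

# log-transform every uwmc_* column of a simulated cohort
log_features <- function(cohort) {
  df <- as.data.frame(cohort)
  for (f in grep("^uwmc_", names(df), value = TRUE)) df[[f]] <- log_transform(df[[f]])
  df
}

feature_names <- function(cohort) grep("^uwmc_", names(cohort), value = TRUE)
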