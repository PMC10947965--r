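#' Streamline-lesion intersection settings
#'
#' @param sampling_step `NULL` (default) uses exact cell traversal: every
#'   voxel whose nearest-neighbour cell a segment geometrically crosses is
#'   tested, however short the crossing chord. A numeric value (mm) instead
#'   densifies each segment to that arc-length spacing and tests only the
#'   sample points, an approximation that can step over chords shorter
#'   than the spacing.
#' @param endpoint_dilation Chebyshev radius (voxels) searched around an
#'   unlabeled endpoint voxel when matching endpoints to regions; 0 means
#'   exact-voxel matching. With dilation, the majority nonzero label in the
#'   neighbourhood is used and ties resolve to "unlabeled".
#' @return A list of class `uwmc_intersection_config`.
#' @export
intersection_config <- function(sampling_step = NULL, endpoint_dilation = 0L) {
  if (!is.null(sampling_step) && sampling_step <= 0)
    abort("`sampling_step` must be positive")
  if (endpoint_dilation < 0) abort("`endpoint_dilation` must be >= 0")
  structure(list(sampling_step = sampling_step,
                 endpoint_dilation = as.integer(endpoint_dilation)),
            class = "uwmc_intersection_config")
}

# Densify a polyline so consecutive points are at most `step` apart.
densify_polyline <- function(pts, step) {
  n <- nrow(pts)
  seg <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  k <- pmax(1L, ceiling(len / step))
  idx <- rep.int(seq_len(n - 1L), k)
  tt <- sequence(k) / rep.int(k, k)
  rbind(pts[1L, , drop = FALSE], pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * tt)
}

# Exact traversal: all 0-based voxel indices whose nearest-neighbour cells a
# polyline crosses. Cells are unit cubes centred on integer voxel
# coordinates, so boundaries sit at half-integers; each segment's crossing
# parameters are enumerated per axis and cells read off interval midpoints.
polyline_cells <- function(pts, inv_affine) {
  v <- cbind(pts, 1) %*% t(inv_affine)
  v <- v[, 1:3, drop = FALSE]
  n <- nrow(v)
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    v0 <- v[s, ]; d <- v[s + 1L, ] - v0
    tt <- numeric(0)
    for (ax in 1:3) {
      if (d[ax] == 0) next
      lo <- min(v0[ax], v0[ax] + d[ax]); hi <- max(v0[ax], v0[ax] + d[ax])
      # cell boundaries k + 0.5 strictly inside (lo, hi)
      k1 <- floor(lo - 0.5) + 1; k2 <- ceiling(hi - 0.5) - 1
      if (k1 > k2) next
      bnd <- (k1:k2) + 0.5
      bnd <- bnd[bnd > lo & bnd < hi]
      tt <- c(tt, (bnd - v0[ax]) / d[ax])
    }
    tt <- sort(unique(c(0, tt, 1)))
    mids <- (tt[-1L] + tt[-length(tt)]) / 2
    out[[s]] <- round(sweep(outer(mids, d), 2, v0, "+"))
  }
  unique(do.call(rbind, out))
}

#' Does a streamline pass through a lesion mask?
#'
#' A streamline passes through the mask iff the polyline geometrically
#' crosses the nearest-neighbour cell of any true voxel (world-to-voxel via
#' the inverse affine): a single touched lesion voxel counts, with no
#' minimum overlap length. The default exact traversal enumerates every
#' crossed cell per segment; setting `sampling_step` in the config instead
#' tests points densified to that spacing. Points outside the grid never
#' hit.
#'
#' @param streamline An n x 3 matrix of world-mm points.
#' @param wmh A binary lesion mask (`uwmc_mask`).
#' @param cfg An [intersection_config()].
#' @return Logical scalar.
#' @export
passes_through <- function(streamline, wmh, cfg = intersection_config()) {
  idx <- if (is.null(cfg$sampling_step)) {
    polyline_cells(streamline, solve(wmh$affine))
  } else {
    world_to_voxel(densify_polyline(streamline, cfg$sampling_step), wmh$affine)
  }
  any(lookup_voxels(wmh$data, idx, outside = FALSE))
}

#' Region labels at a streamline's two endpoints
#'
#' @param streamline An n x 3 matrix of world-mm points.
#' @param labels A parcellation (`uwmc_labels`).
#' @param cfg An [intersection_config()]; `endpoint_dilation` controls the
#'   search around unlabeled endpoint voxels.
#' @return Integer vector of length 2; `NA` where the endpoint is unlabeled.
#' @export
endpoint_labels <- function(streamline, labels, cfg = intersection_config()) {
  ends <- streamline[c(1L, nrow(streamline)), , drop = FALSE]
  idx <- world_to_voxel(ends, labels$affine)
  vals <- lookup_voxels(labels$data, idx, outside = 0L)
  d <- cfg$endpoint_dilation
  out <- integer(2)
  for (e in 1:2) {
    v <- vals[e]
    if (v == 0L && d > 0L) v <- majority_label(labels$data, idx[e, ], d)
    out[e] <- if (v == 0L) NA_integer_ else v
  }
  out
}

majority_label <- function(data, center, d) {
  off <- as.matrix(expand.grid(-d:d, -d:d, -d:d))
  nb <- sweep(off, 2, as.numeric(center), "+")
  vals <- lookup_voxels(data, nb, outside = 0L)
  vals <- vals[!is.na(vals) & vals != 0L]
  if (!length(vals)) return(0L)
  tab <- sort(table(vals), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return(0L)  # tie -> unlabeled
  as.integer(names(tab)[1])
}

#' Count end-to-end connections and lesion-crossing streamlines per region pair
#'
#' A streamline contributes to the unordered pair \{a, b\} iff its two
#' endpoint voxels carry two distinct nonzero labels a and b; it always
#' increments the pair's total count T and additionally its unhealthy count
#' U iff it passes through the lesion mask. Streamlines with an unlabeled
#' end, or with both ends in the same region, are ignored.
#'
#' @param streamlines An `uwmc_streamlines` object (world mm).
#' @param labels An `uwmc_labels` parcellation.
#' @param wmh An `uwmc_mask` lesion mask on the same grid.
#' @param cfg An [intersection_config()].
#' @return A tibble of class `uwmc_counts` with columns `a`, `b` (label ids,
#'   `a < b`), `total`, `unhealthy`, sorted by (a, b).
#' @export
count_connections <- function(streamlines, labels, wmh, cfg = intersection_config()) {
  stopifnot_same_grid(labels, wmh)
  inv <- solve(wmh$affine)
  keys <- character(0); tot <- uh <- integer(0)
  pos <- new.env(parent = emptyenv())
  for (p in streamlines$streamlines) {
    ends <- endpoint_labels(p, labels, cfg)
    if (anyNA(ends) || ends[1] == ends[2]) next
    a <- min(ends); b <- max(ends)
    key <- paste0(a, "_", b)
    idx <- if (is.null(cfg$sampling_step)) polyline_cells(p, inv)
           else world_to_voxel(densify_polyline(p, cfg$sampling_step), wmh$affine, inv)
    crossing <- any(lookup_voxels(wmh$data, idx, outside = FALSE))
    if (is.null(pos[[key]])) {
      keys <- c(keys, key); tot <- c(tot, 0L); uh <- c(uh, 0L)
      pos[[key]] <- length(keys)
    }
    i <- pos[[key]]
    tot[i] <- tot[i] + 1L
    if (crossing) uh[i] <- uh[i] + 1L
  }
  ab <- if (length(keys)) {
    do.call(rbind, lapply(strsplit(keys, "_"), as.integer))
  } else matrix(integer(0), 0, 2)
  out <- tibble(a = ab[, 1], b = ab[, 2], total = tot, unhealthy = uh)
  out <- dplyr::arrange(out, .data$a, .data$b)
  class(out) <- c("uwmc_counts", class(out))
  out
}

#' Pairwise unhealthy white matter connectivity
#'
#' For each unordered region pair, UWMC = U / T: the proportion of
#' end-to-end streamlines between the two regions that pass through the
#' lesion mask. Pairs with T = 0 are recorded with UWMC 0 and flagged
#' (`zero_denominator`), a convention that lets the downstream log transform
#' apply its zero substitution rather than dropping the pair.
#'
#' @param counts An `uwmc_counts` tibble from [count_connections()].
#' @param labels Optional `uwmc_labels` (or label table) used to attach
#'   region names.
#' @return A tibble of class `uwmc_matrix` with columns `a`, `b`,
#'   (`a_name`, `b_name` when names are available,) `total`, `unhealthy`,
#'   `uwmc`, `zero_denominator`.
#' @export
pairwise_uwmc <- function(counts, labels = NULL) {
  stopifnot(all(counts$unhealthy <= counts$total))
  out <- dplyr::mutate(as_tibble(counts),
    uwmc = ifelse(.data$total > 0, .data$unhealthy / .data$total, 0),
    zero_denominator = .data$total == 0L)
  if (!is.null(labels)) {
    tab <- if (inherits(labels, "uwmc_labels")) labels$table else validate_label_table(labels)
    nm <- stats::setNames(tab$name, tab$id)
    out <- dplyr::mutate(out,
      a_name = unname(nm[as.character(.data$a)]),
      b_name = unname(nm[as.character(.data$b)]),
      .after = "b")
  }
  class(out) <- c("uwmc_matrix", class(out))
  out
}

lobe_of <- function(labels, ids) {
  tab <- labels$table
  unname(stats::setNames(tab$lobe, tab$id)[as.character(ids)])
}

#' Lobar and global UWMC aggregates
#'
#' Lobar UWMC for a bilateral lobe is the ratio of sums over all pairs with
#' both regions in that lobe: sum of unhealthy counts divided by sum of
#' totals (not a mean of per-pair ratios). Global UWMC is the same ratio
#' over every pair in the connectome, inter-lobe pairs included.
#'
#' @param counts An `uwmc_counts` tibble.
#' @param labels An `uwmc_labels` parcellation whose table assigns a lobe to
#'   every region appearing in `counts`.
#' @return `lobar_uwmc()`: a tibble with columns `lobe`, `total`,
#'   `unhealthy`, `uwmc`, `zero_denominator`. `global_uwmc()`: a single
#'   number; errors when the connectome has no streamlines.
#' @export
lobar_uwmc <- function(counts, labels) {
  la <- lobe_of(labels, counts$a)
  lb <- lobe_of(labels, counts$b)
  if (anyNA(la) || anyNA(lb))
    abort("every region in `counts` needs a lobe assignment in the label table")
  within <- counts[!is.na(la) & la == lb, ]
  within$lobe <- la[la == lb]
  out <- dplyr::summarise(dplyr::group_by(within, .data$lobe),
                          total = sum(.data$total),
                          unhealthy = sum(.data$unhealthy), .groups = "drop")
  # lobes present in the table but with no within-lobe pairs still appear, flagged
  all_lobes <- intersect(VALID_LOBES, unique(labels$table$lobe))
  out <- dplyr::left_join(tibble(lobe = all_lobes), out, by = "lobe")
  out <- dplyr::mutate(out,
    total = dplyr::coalesce(.data$total, 0L),
    unhealthy = dplyr::coalesce(.data$unhealthy, 0L),
    uwmc = ifelse(.data$total > 0, .data$unhealthy / .data$total, 0),
    zero_denominator = .data$total == 0L)
  out
}

#' @rdname lobar_uwmc
#' @export
global_uwmc <- function(counts) {
  if (nrow(counts) == 0 || sum(counts$total) == 0)
    abort("empty connectome: no streamline connects any region pair")
  sum(counts$unhealthy) / sum(counts$total)
}

#' Extract UWMC for pathology-vulnerable region pairs
#'
#' Returns all unordered pairs whose two regions are both flagged for the
#' chosen pathology set in the label table (`in_abeta_set` /
#' `in_tau_set`), in canonical (min id, max id) order. Pairs absent from
#' `matrix` (no streamline observed) are included with UWMC 0 and the
#' zero-denominator flag, so the candidate set always has exactly
#' n(n-1)/2 entries for n flagged regions.
#'
#' @param matrix An `uwmc_matrix` tibble from [pairwise_uwmc()].
#' @param labels An `uwmc_labels` parcellation (or label table).
#' @param set `"abeta"` or `"tau"`.
#' @return A tibble with columns `a`, `b`, `a_name`, `b_name`, `uwmc`,
#'   `zero_denominator`.
#' @export
pathology_subset <- function(matrix, labels, set = c("abeta", "tau")) {
  set <- match.arg(set)
  tab <- if (inherits(labels, "uwmc_labels")) labels$table else validate_label_table(labels)
  flag <- if (set == "abeta") tab$in_abeta_set else tab$in_tau_set
  ids <- sort(tab$id[flag])
  if (length(ids) < 2)
    abort(sprintf("pathology set '%s' has fewer than 2 flagged regions", set))
  pairs <- t(utils::combn(ids, 2L))
  nm <- stats::setNames(tab$name, tab$id)
  out <- tibble(a = pairs[, 1], b = pairs[, 2],
                a_name = unname(nm[as.character(pairs[, 1])]),
                b_name = unname(nm[as.character(pairs[, 2])]))
  m <- as_tibble(matrix)[, intersect(c("a", "b", "uwmc", "zero_denominator"), names(matrix))]
  out <- dplyr::left_join(out, m, by = c("a", "b"))
  dplyr::mutate(out,
    uwmc = dplyr::coalesce(.data$uwmc, 0),
    zero_denominator = dplyr::coalesce(.data$zero_denominator, TRUE))
}

#' Write or read a long-format pair table
#'
#' Columns: `region_a_id`, `region_a_name`, `region_b_id`, `region_b_name`,
#' `total_count`, `unhealthy_count`, `uwmc`, `zero_denominator_flag`; rows
#' sorted by (min id, max id). CSV, UTF-8, '.' decimal separator.
#'
#' @param matrix An `uwmc_matrix` tibble (ideally with names attached).
#' @param path Output CSV path.
#' @return `write_pair_table()`: `path` invisibly; `read_pair_table()`: the
#'   tibble, with the same column layout [pairwise_uwmc()] produces.
#' @export
write_pair_table <- function(matrix, path) {
  df <- as_tibble(matrix)
  if (!"a_name" %in% names(df)) df$a_name <- NA_character_
  if (!"b_name" %in% names(df)) df$b_name <- NA_character_
  out <- tibble(region_a_id = df$a, region_a_name = df$a_name,
                region_b_id = df$b, region_b_name = df$b_name,
                total_count = df$total, unhealthy_count = df$unhealthy,
                uwmc = df$uwmc, zero_denominator_flag = df$zero_denominator)
  out <- dplyr::arrange(out, .data$region_a_id, .data$region_b_id)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(a = as.integer(df$region_a_id), b = as.integer(df$region_b_id),
                a_name = as.character(df$region_a_name),
                b_name = as.character(df$region_b_name),
                total = as.integer(df$total_count),
                unhealthy = as.integer(df$unhealthy_count),
                uwmc = df$uwmc, zero_denominator = df$zero_denominator_flag)
  class(out) <- c("uwmc_matrix", class(out))
  out
}

#' Heatmap of pairwise UWMC
#'
#' @param matrix An `uwmc_matrix` tibble.
#' @return A ggplot object.
#' @export
plot_uwmc_matrix <- function(matrix) {
  df <- as_tibble(matrix)
  df$a_lab <- if ("a_name" %in% names(df) && !anyNA(df$a_name)) df$a_name else factor(df$a)
  df$b_lab <- if ("b_name" %in% names(df) && !anyNA(df$b_name)) df$b_name else factor(df$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a_lab, y = .data$b_lab, fill = .data$uwmc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "UWMC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
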