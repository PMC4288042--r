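#' Grid-size heuristic for an emergent SOM
#'
#' Nodes ~ 2 * n (capped at 4000) arranged as a golden-ratio rectangle,
#' never smaller than 10 x 16. Emergent maps carry more nodes than samples
#' so that cluster structure appears as U-matrix topography rather than as
#' one-node-per-cluster vector quantization; maps sized near or below the
#' sample count leave ridges too thin for reliable automatic segmentation.
#'
#' @param n Number of training samples.
#' @return Integer vector `c(rows, cols)`.
#' @export
som_grid_size <- function(n) {
  nodes <- min(max(2 * n, 160), 4000)
  phi <- (1 + sqrt(5)) / 2
  rows <- max(10L, as.integer(round(sqrt(nodes / phi))))
  cols <- max(16L, as.integer(ceiling(nodes / rows)))
  c(rows, cols)
}

# toroidal squared grid distance from node (r, c) to all nodes
torus_dist2 <- function(rows, cols, node_r, node_c, toroidal = TRUE) {
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  dr <- abs(r - node_r)
  dc <- abs(c - node_c)
  if (toroidal) {
    dr <- pmin(dr, rows - dr)
    dc <- pmin(dc, cols - dc)
  }
  dr^2 + dc^2
}

#' Train an emergent self-organizing map
#'
#' Classical online SOM: for each presented sample the best-matching unit
#' (BMU) is found by Euclidean distance and all node weights are pulled
#' toward the sample under a Gaussian neighborhood on the (by default
#' toroidal) grid, with learning rate and neighborhood radius decaying
#' exponentially over the run. Sample presentation order is reshuffled
#' every epoch under the seeded RNG, so training does not depend on input
#' row order beyond the seed. Deterministic for a fixed seed.
#'
#' @param x Numeric matrix (rows = samples) or a [tetra_profiles()] tibble.
#' @param rows,cols Grid dimensions; defaults from [som_grid_size()].
#' @param epochs Training epochs (default 20).
#' @param radius_start,radius_end Neighborhood radius decay endpoints;
#'   default half the smaller grid dimension down to 1.
#' @param rate_start,rate_end Learning-rate decay endpoints (default 0.5 to
#'   0.05).
#' @param toroidal Wrap the grid edges (default `TRUE`).
#' @param seed Integer seed.
#' @return Object of class `som_grid`: weights (nodes x features, row-major
#'   node order), grid dimensions, config, and the per-epoch mean
#'   quantization error trace `qe` (index 1 = at initialization).
#' @export
som_train <- function(x, rows = NULL, cols = NULL, epochs = 20,
                      radius_start = NULL, radius_end = 1,
                      rate_start = 0.5, rate_end = 0.05,
                      toroidal = TRUE, seed = 1) {
  if (is.data.frame(x)) x <- profile_matrix(x)
  stopifnot(is.matrix(x), nrow(x) >= 1)
  if (!all(is.finite(x))) abort("training matrix contains non-finite values")
  if (nrow(x) == 1) warn("training on a single sample; map will be degenerate")
  n <- nrow(x); d <- ncol(x)
  if (is.null(rows) || is.null(cols)) {
    gs <- som_grid_size(n)
    if (is.null(rows)) rows <- gs[1]
    if (is.null(cols)) cols <- gs[2]
  }
  if (is.null(radius_start)) radius_start <- min(rows, cols) / 2
  stopifnot(radius_start >= radius_end, radius_end > 0,
            rate_start >= rate_end, rate_end > 0, rate_start <= 1)
  n_nodes <- rows * cols
  node_r <- rep(seq_len(rows), each = cols)
  node_c <- rep(seq_len(cols), times = rows)
  qe_of <- function(W) {
    mean(vapply(seq_len(n), function(i) {
      sqrt(min(rowSums(sweep(W, 2, x[i, ])^2)))
    }, numeric(1)))
  }
  # canonical content order: presentation depends on the sample values, not
  # on input row order, so permuting rows leaves training untouched
  canon <- do.call(order, as.data.frame(x))
  res <- withr::with_seed(seed, {
    # uniform random init inside the per-feature data range
    rng <- apply(x, 2, range)
    W <- matrix(runif(n_nodes * d, rep(rng[1, ], each = n_nodes),
                      rep(rng[2, ], each = n_nodes)), n_nodes, d)
    qe <- numeric(epochs + 1)
    qe[1] <- qe_of(W)
    total_steps <- epochs * n
    step <- 0
    for (epoch in seq_len(epochs)) {
      ord <- canon[sample.int(n)]
      for (i in ord) {
        frac <- step / max(total_steps - 1, 1)
        sigma <- radius_start * (radius_end / radius_start)^frac
        alpha <- rate_start * (rate_end / rate_start)^frac
        xi <- x[i, ]
        diff <- sweep(W, 2, xi)
        bmu <- which.min(rowSums(diff^2))
        h <- exp(-torus_dist2(rows, cols, node_r[bmu], node_c[bmu],
                              toroidal) / (2 * sigma^2))
        W <- W - (alpha * h) * diff
        step <- step + 1
      }
      qe[epoch + 1] <- qe_of(W)
    }
    list(W = W, qe = qe)
  })
  structure(list(
    weights = res$W, rows = rows, cols = cols, toroidal = toroidal,
    epochs = epochs, radius_start = radius_start, radius_end = radius_end,
    rate_start = rate_start, rate_end = rate_end, seed = seed,
    qe = res$qe, features = colnames(x)
  ), class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf(
    "som_grid: %d x %d (%s), %d features, %d epochs, QE %.4g -> %.4g\n",
    x$rows, x$cols, if (x$toroidal) "toroidal" else "planar",
    length(x$features), x$epochs, x$qe[1], x$qe[length(x$qe)]))
  invisible(x)
}

#' @export
glance.som_grid <- function(x, ...) {
  tibble(rows = x$rows, cols = x$cols, toroidal = x$toroidal,
         epochs = x$epochs, seed = x$seed,
         qe_init = x$qe[1], qe_final = x$qe[length(x$qe)])
}

#' @export
tidy.som_grid <- function(x, ...) {
  u <- som_umatrix(x)
  tibble(row = rep(seq_len(x$rows), each = x$cols),
         col = rep(seq_len(x$cols), times = x$rows),
         umatrix = as.vector(t(u)))
}

#' Best-matching unit of a vector
#'
#' Returns the grid coordinates of the node whose weight vector is nearest
#' (Euclidean) to `v`; ties break to the lexicographically smallest
#' (row, col).
#'
#' @param grid A trained [som_train()] object.
#' @param v Numeric vector matching the grid's feature dimension.
#' @return Integer vector `c(row, col)` (1-based).
#' @export
som_bmu <- function(grid, v) {
  stopifnot(is(grid, "som_grid"))
  if (length(v) != ncol(grid$weights)) {
    abort(sprintf("vector length %d does not match feature dimension %d",
                  length(v), ncol(grid$weights)))
  }
  d2 <- rowSums(sweep(grid$weights, 2, v)^2)
  idx <- which.min(d2)  # weights are stored row-major, so the first minimum
                        # is the lexicographically smallest (row, col)
  c(row = ((idx - 1L) %/% grid$cols) + 1L,
    col = ((idx - 1L) %% grid$cols) + 1L)
}

# BMU node index (row-major) for every row of a matrix
som_bmu_index <- function(grid, x) {
  W <- grid$weights
  w2 <- rowSums(W^2)
  # argmin_j ||x_i - w_j||^2 = argmin_j (w2_j - 2 x_i . w_j)
  cross <- x %*% t(W)
  apply(sweep(-2 * cross, 2, w2, `+`), 1, which.min)
}

torus_neighbors <- function(rows, cols, connectivity = 8, toroidal = TRUE) {
  offs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  }
  idx <- seq_len(rows * cols)
  r <- ((idx - 1L) %/% cols) + 1L
  c <- ((idx - 1L) %% cols) + 1L
  lapply(idx, function(i) {
    nr <- r[i] + offs[, 1]
    nc <- c[i] + offs[, 2]
    if (toroidal) {
      nr <- ((nr - 1) %% rows) + 1
      nc <- ((nc - 1) %% cols) + 1
    } else {
      keep <- nr >= 1 & nr <= rows & nc >= 1 & nc <= cols
      nr <- nr[keep]; nc <- nc[keep]
    }
    unique((nr - 1L) * cols + nc)
  })
}

#' U-matrix of a trained map
#'
#' Per node, the mean Euclidean distance between its weight vector and
#' those of its topological neighbors (4- or 8-connected, toroidal wrapping
#' per the grid). High ridges separate clusters on an emergent map.
#'
#' @param grid A trained [som_train()] object.
#' @param connectivity 4 or 8 (default 8).
#' @return Numeric `rows x cols` matrix, all entries >= 0.
#' @export
som_umatrix <- function(grid, connectivity = 8) {
  stopifnot(is(grid, "som_grid"), connectivity %in% c(4, 8))
  nb <- torus_neighbors(grid$rows, grid$cols, connectivity, grid$toroidal)
  W <- grid$weights
  u <- vapply(seq_along(nb), function(i) {
    mean(sqrt(rowSums(sweep(W[nb[[i]], , drop = FALSE], 2, W[i, ])^2)))
  }, numeric(1))
  matrix(u, grid$rows, grid$cols, byrow = TRUE)
}

#' @export
autoplot.som_grid <- function(object, connectivity = 8, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$umatrix)) +
    geom_tile() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(title = "U-matrix", x = "map column", y = "map row",
         fill = "mean neighbor\ndistance") +
    theme_minimal()
}

#' Extract genome bins from a trained map
#'
#' Automates map segmentation with a deterministic rule: nodes whose
#' U-value exceeds the `quantile` threshold (computed over all map nodes)
#' are removed as boundary ridge, the surviving nodes are split into
#' connected components on the (toroidal) grid, windows inherit the
#' component of their BMU, and each contig takes the majority bin of its
#' windows (ties: unassigned).
#'
#' @param grid A trained [som_train()] object.
#' @param profiles The [tetra_profiles()] tibble the map was trained on (or
#'   any profile tibble with matching features).
#' @param quantile U-value quantile above which data-bearing nodes are
#'   removed (default 0.5); `1` removes nothing and yields a single bin.
#' @param connectivity 4 or 8 (default 8).
#' @param unassigned What to do with windows whose BMU sits on the removed
#'   ridge: `"nearest"` (default) re-assigns them to the component of the
#'   nearest retained node in weight space — every window then carries a
#'   bin; `"drop"` leaves them unassigned, the strict inherit-your-BMU
#'   rule.
#' @return Object of class `bin_assignment`: list with `windows` (tibble
#'   `window_id`, `contig_id`, `bin_id` — `NA` = unassigned), `contigs`
#'   (tibble `contig_id`, `bin_id`, `n_windows`, `n_assigned`) and `nodes`
#'   (tibble `row`, `col`, `umatrix`, `n_windows`, `bin_id`).
#' @export
som_bins <- function(grid, profiles, quantile = 0.5, connectivity = 8,
                     unassigned = c("nearest", "drop")) {
  stopifnot(is(grid, "som_grid"))
  unassigned <- match.arg(unassigned)
  x <- profile_matrix(profiles)
  if (ncol(x) != ncol(grid$weights)) {
    abort("profile features do not match the trained grid")
  }
  bmu <- som_bmu_index(grid, x)
  u <- as.vector(t(som_umatrix(grid, connectivity)))
  thr <- stats::quantile(u, quantile)
  keep <- which(u <= thr)
  node_bin <- rep(NA_integer_, grid$rows * grid$cols)
  if (length(keep) == 0) {
    warn("U-matrix threshold removed every data-bearing node; no bins extracted")
  } else {
    nb <- torus_neighbors(grid$rows, grid$cols, connectivity, grid$toroidal)
    edges <- purrr::map_dfr(keep, function(i) {
      j <- intersect(nb[[i]], keep)
      j <- j[j > i]
      if (length(j) == 0) NULL else tibble(from = as.character(i),
                                           to = as.character(j))
    })
    g <- igraph::graph_from_data_frame(
      if (nrow(edges) > 0) edges else tibble(from = character(0), to = character(0)),
      directed = FALSE, vertices = tibble(name = as.character(keep)))
    comp <- igraph::components(g)
    node_bin[keep] <- comp$membership[as.character(keep)]
  }
  win_bin <- node_bin[bmu]
  if (unassigned == "nearest" && anyNA(win_bin) && length(keep) > 0) {
    ridge <- which(is.na(win_bin))
    Wk <- grid$weights[keep, , drop = FALSE]
    w2 <- rowSums(Wk^2)
    cross <- x[ridge, , drop = FALSE] %*% t(Wk)
    nearest <- apply(sweep(-2 * cross, 2, w2, `+`), 1, which.min)
    win_bin[ridge] <- node_bin[keep[nearest]]
  }
  windows <- tibble(
    window_id = profiles$window_id,
    contig_id = profiles$contig_id,
    node = bmu,
    bin_id = if_else(is.na(win_bin), NA_character_,
                     sprintf("bin_%02d", win_bin))
  )
  contigs <- windows %>%
    group_by(.data$contig_id) %>%
    summarise(n_windows = dplyr::n(),
              n_assigned = sum(!is.na(.data$bin_id)),
              bin_id = majority_label(.data$bin_id),
              .groups = "drop")
  nodes <- tibble(
    row = rep(seq_len(grid$rows), each = grid$cols),
    col = rep(seq_len(grid$cols), times = grid$rows),
    umatrix = u,
    n_windows = tabulate(bmu, nbins = grid$rows * grid$cols),
    bin_id = if_else(is.na(node_bin), NA_character_,
                     sprintf("bin_%02d", node_bin))
  )
  structure(list(windows = select(windows, -"node"), contigs = contigs,
                 nodes = nodes, quantile = quantile,
                 connectivity = connectivity),
            class = "bin_assignment")
}

# majority label among non-NA votes; ties -> NA
majority_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(NA_character_)
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
  names(tab)[1]
}

#' @export
print.bin_assignment <- function(x, ...) {
  nb <- dplyr::n_distinct(x$contigs$bin_id, na.rm = TRUE)
  cat(sprintf(
    "bin_assignment: %d bins, %d/%d contigs assigned (%d/%d windows)\n",
    nb, sum(!is.na(x$contigs$bin_id)), nrow(x$contigs),
    sum(!is.na(x$windows$bin_id)), nrow(x$windows)))
  invisible(x)
}

#' @export
tidy.bin_assignment <- function(x, ...) {
  x$windows
}

#' @export
glance.bin_assignment <- function(x, ...) {
  tibble(n_bins = dplyr::n_distinct(x$contigs$bin_id, na.rm = TRUE),
         n_contigs = nrow(x$contigs),
         n_contigs_assigned = sum(!is.na(x$contigs$bin_id)),
         n_windows = nrow(x$windows),
         n_windows_assigned = sum(!is.na(x$windows$bin_id)),
         umatrix_quantile = x$quantile)
}

#' @export
autoplot.bin_assignment <- function(object, ...) {
  ggplot(object$nodes,
         aes(x = .data$col, y = .data$row, fill = .data$bin_id)) +
    geom_tile() +
    coord_equal() +
    labs(title = "Map segmentation", x = "map column", y = "map row",
         fill = "bin") +
    theme_minimal()
}

#' Adjusted Rand index of a bin assignment against ground truth
#'
#' Chance-corrected agreement between contig-level bins and the true
#' contig-to-genome map, computed over contigs that received a bin
#' (unassigned contigs carry no prediction to score).
#'
#' @param assignment A [som_bins()] result, or a tibble with `contig_id`
#'   and `bin_id`.
#' @param truth Tibble `contig_id`, `genome_id` (see [ground_truth()]).
#' @return Single numeric ARI.
#' @export
bin_ari <- function(assignment, truth) {
  ctg <- if (is(assignment, "bin_assignment")) assignment$contigs else assignment
  joined <- ctg %>%
    filter(!is.na(.data$bin_id)) %>%
    left_join(truth, by = "contig_id")
  if (nrow(joined) == 0) return(NA_real_)
  mclust::adjustedRandIndex(joined$bin_id, joined$genome_id)
}

#' Export map weights or U-matrix as TSV
#'
#' @param grid A trained [som_train()] object.
#' @param path Output file.
#' @export
write_som_weights <- function(grid, path) {
  df <- as_tibble(as.data.frame(grid$weights))
  names(df) <- grid$features
  df <- dplyr::bind_cols(
    tibble(row = rep(seq_len(grid$rows), each = grid$cols),
           col = rep(seq_len(grid$cols), times = grid$rows)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_som_weights
#' @export
write_umatrix <- function(grid, path) {
  readr::write_tsv(tidy(grid), path)
  invisible(path)
}

#' Export a bin assignment as TSV
#'
#' @param assignment A [som_bins()] result.
#' @param path Output file.
#' @export
write_bins <- function(assignment, path) {
  readr::write_tsv(assignment$windows, path)
  invisible(path)
}
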