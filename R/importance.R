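#' Compose PCA conditioning and a learned projection
#'
#' The full map from original feature space to the learned space is
#' `B = (Q * s) %*% A`: PCA loadings (including the total-variance scale)
#' followed by the metric-learning projection.
#'
#' @param pca a `pca_model` from [pca_condition_fit()].
#' @param proj a [linear_projection()] fitted on the PCA-conditioned data.
#' @return d x p numeric matrix `B`.
#' @export
compose_projection <- function(pca, proj) {
  if (ncol(pca$Q) != proj$d_in)
    stop(sprintf("PCA model emits %d dims but the projection expects %d",
                 ncol(pca$Q), proj$d_in), call. = FALSE)
  (pca$Q * pca$scale_factor) %*% proj$A
}

#' Sort a composite projection by singular value
#'
#' Distances in the projected space are invariant to any orthogonal
#' right-rotation of `B`, so an order must be imposed before columns can be
#' interpreted individually. The SVD `B = U D V'` gives the sorted projection
#' `B~ = U D` with singular values descending. For reproducibility the sign
#' of each left singular vector is fixed so its largest-magnitude entry is
#' positive.
#'
#' @param B d x p numeric matrix (nonzero).
#' @return a `sorted_projection`: list with `B_tilde` (d x p), `singular_values`,
#'   `V` (p x p right singular vectors), and `B`.
#' @export
sort_projection <- function(B) {
  B <- as.matrix(B)
  if (all(B == 0)) stop("`B` is identically zero; nothing to sort", call. = FALSE)
  sv <- svd(B)
  U <- sv$u; V <- sv$v
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  structure(list(B_tilde = U %*% diag(sv$d, nrow = length(sv$d)),
                 singular_values = sv$d, V = V, B = B),
            class = "sorted_projection")
}

#' Per-channel importance of a sorted projection
#'
#' For each projected dimension j, the importance of channel k is the fraction
#' of the column's squared Euclidean norm carried by that channel's rows:
#' \deqn{importance(ch_k, j) = \sum_{i \in I_k} \tilde B_{ij}^2 \Big/
#'   \sum_{i'} \tilde B_{i'j}^2.}
#' The overall importance is the uniform mean over the p columns. Columns with
#' zero singular value are 0/0; they are assigned the uniform value 1/N_ch and
#' flagged in `degenerate_dims`.
#'
#' @param sp a `sorted_projection` from [sort_projection()].
#' @param channel_index_map named list mapping each channel to its row
#'   indices in `B` (a partition of `1:d`), e.g. the `channel_index_map`
#'   attribute of a `feature_matrix`.
#' @return an `importance_map`: list with `per_dim` (N_ch x p, columns sum to
#'   1), `overall` (length N_ch, sums to 1), `channels`, `degenerate_dims`.
#' @export
channel_importance <- function(sp, channel_index_map) {
  Bt <- sp$B_tilde
  d <- nrow(Bt)
  idx_all <- sort(as.integer(unlist(channel_index_map, use.names = FALSE)))
  if (!identical(idx_all, seq_len(d)))
    stop("`channel_index_map` must partition the rows of B", call. = FALSE)
  nch <- length(channel_index_map)
  p <- ncol(Bt)
  sq <- Bt^2
  col_tot <- colSums(sq)
  per_dim <- matrix(0, nch, p,
                    dimnames = list(names(channel_index_map), NULL))
  degenerate <- which(col_tot <= .Machine$double.eps * d)
  for (k in seq_len(nch)) {
    rows <- channel_index_map[[k]]
    per_dim[k, ] <- colSums(sq[rows, , drop = FALSE]) / col_tot
  }
  if (length(degenerate)) per_dim[, degenerate] <- 1 / nch
  structure(list(per_dim = per_dim, overall = rowMeans(per_dim),
                 channels = names(channel_index_map),
                 degenerate_dims = degenerate),
            class = "importance_map")
}

#' Approximate 2-D scalp positions for the 10/20 montage
#'
#' Head is the unit circle, nose at (0, 1). A1/A2 sit at the ears just
#' outside the circle. Intended for topographic display, not source analysis.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
montage_1020 <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4", "Cz",
                "T3", "T4", "T5", "T6", "P3", "P4", "Pz", "O1", "O2",
                "A1", "A2"),
    x = c(-0.309, 0.309, -0.45, 0.45, -0.809, 0.809, 0, -0.5, 0.5, 0,
          -1, 1, -0.809, 0.809, -0.45, 0.45, 0, -0.309, 0.309,
          -1.15, 1.15),
    y = c(0.951, 0.951, 0.51, 0.51, 0.588, 0.588, 0.5, 0, 0, 0,
          0, 0, -0.588, -0.588, -0.51, -0.51, -0.5, -0.951, -0.951,
          -0.1, -0.1),
    stringsAsFactors = FALSE
  )
}

# inverse-distance-weighted interpolation of channel values on a grid
.idw_field <- function(coords, values, gx, gy, power = 2) {
  field <- matrix(NA_real_, length(gx), length(gy))
  for (ix in seq_along(gx)) {
    dx <- gx[ix] - coords$x
    for (iy in seq_along(gy)) {
      d2 <- dx^2 + (gy[iy] - coords$y)^2
      if (any(d2 < 1e-12)) {
        field[ix, iy] <- values[which.min(d2)]
      } else {
        w <- 1 / d2^(power / 2)
        field[ix, iy] <- sum(w * values) / sum(w)
      }
    }
  }
  field
}

#' Export an importance map as CSV and topographic images
#'
#' Writes `<path>/importance.csv` (long format: channel, dim, importance; dim
#' 0 is the overall map) and one PNG per projected dimension plus the overall
#' map, rendered as an inverse-distance-interpolated scalp field on the 10/20
#' montage.
#'
#' @param imp an `importance_map`.
#' @param path output directory (created if missing).
#' @param render logical; skip PNG rendering when `FALSE`.
#' @return invisibly, the paths written.
#' @export
topomap_export <- function(imp, path, render = TRUE) {
  mont <- montage_1020()
  unknown <- setdiff(imp$channels, mont$channel)
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "),
         "; resolvable names are: ", paste(mont$channel, collapse = ", "),
         call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- ncol(imp$per_dim)
  long <- rbind(
    data.frame(channel = imp$channels, dim = 0L, importance = imp$overall),
    do.call(rbind, lapply(seq_len(p), function(j) {
      data.frame(channel = imp$channels, dim = j,
                 importance = imp$per_dim[, j])
    }))
  )
  csv <- file.path(path, "importance.csv")
  utils::write.csv(long, csv, row.names = FALSE)
  written <- csv
  if (render) {
    coords <- mont[match(imp$channels, mont$channel), ]
    draw <- function(values, file, title) {
      grDevices::png(file, width = 640, height = 640)
      on.exit(grDevices::dev.off())
      gx <- seq(-1.3, 1.3, length.out = 80)
      gy <- gx
      field <- .idw_field(coords, values, gx, gy)
      outside <- outer(gx^2, gy^2, "+") > 1.3^2
      field[outside] <- NA
      graphics::image(gx, gy, field, asp = 1, axes = FALSE, xlab = "",
                      ylab = "", main = title,
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
      th <- seq(0, 2 * pi, length.out = 200)
      graphics::lines(cos(th), sin(th))
      graphics::lines(c(-0.08, 0, 0.08), c(0.995, 1.08, 0.995))
      graphics::points(coords$x, coords$y, pch = 20)
      graphics::text(coords$x, coords$y, coords$channel, pos = 3, cex = 0.7)
    }
    f <- file.path(path, "topomap_overall.png")
    draw(imp$overall, f, "overall importance")
    written <- c(written, f)
    for (j in seq_len(p)) {
      f <- file.path(path, sprintf("topomap_dim%d.png", j))
      draw(imp$per_dim[, j], f, sprintf("importance, dimension %d", j))
      written <- c(written, f)
    }
  }
  invisible(written)
}
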