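#' Large-sample variance of a Pearson correlation
#'
#' `var(r) = (1 - rho^2)^2 / n`, the asymptotic sampling variance of a
#' correlation coefficient computed from `n` bivariate-normal observations.
#'
#' @param rho True (or plug-in) correlation, strictly inside (-1, 1).
#' @param n Sample size (>= 5).
#' @param denominator `"n"` (default) or `"n-1"`; large-sample variants differ
#'   in the denominator and the choice is surfaced rather than silently made.
#' @return Sampling variance (vectorized over `rho`/`n`).
#' @export
cor_variance <- function(rho, n, denominator = c("n", "n-1")) {
  .check_rho(rho); .check_n(n)
  d <- .denom(n, match.arg(denominator))
  (1 - rho^2)^2 / d
}

#' Large-sample covariance of two correlations sharing a variable
#'
#' For correlations `r_st` and `r_su` computed from the same sample and
#' sharing variable s:
#' `n cov = rho_tu (1 - rho_st^2 - rho_su^2) -
#'   0.5 rho_st rho_su (1 - rho_st^2 - rho_su^2 - rho_tu^2)`.
#' Setting t = u recovers [cor_variance()].
#'
#' @param rho_tu Correlation between the two non-shared variables.
#' @param rho_st,rho_su The two correlations whose sampling covariance is
#'   sought.
#' @inheritParams cor_variance
#' @return Sampling covariance of (r_st, r_su).
#' @export
cor_covariance_shared <- function(rho_tu, rho_st, rho_su, n,
                                  denominator = c("n", "n-1")) {
  .check_rho(c(rho_tu, rho_st, rho_su)); .check_n(n)
  d <- .denom(n, match.arg(denominator))
  (rho_tu * (1 - rho_st^2 - rho_su^2) -
      0.5 * rho_st * rho_su * (1 - rho_st^2 - rho_su^2 - rho_tu^2)) / d
}

#' Large-sample covariance of two correlations with no shared variable
#'
#' Olkin–Siotani expression for `cov(r_st, r_uv)` over four distinct
#' variables s, t, u, v:
#' `n cov = 0.5 rho_st rho_uv (rho_su^2 + rho_sv^2 + rho_tu^2 + rho_tv^2)
#'   + rho_su rho_tv + rho_sv rho_tu
#'   - (rho_st rho_su rho_sv + rho_st rho_tu rho_tv +
#'      rho_uv rho_su rho_tu + rho_uv rho_sv rho_tv)`.
#'
#' @param rho_st,rho_uv The two correlations whose sampling covariance is
#'   sought.
#' @param rho_su,rho_sv,rho_tu,rho_tv Cross-pair correlations.
#' @inheritParams cor_variance
#' @return Sampling covariance of (r_st, r_uv).
#' @export
cor_covariance_general <- function(rho_st, rho_uv, rho_su, rho_sv,
                                   rho_tu, rho_tv, n,
                                   denominator = c("n", "n-1")) {
  .check_rho(c(rho_st, rho_uv, rho_su, rho_sv, rho_tu, rho_tv)); .check_n(n)
  d <- .denom(n, match.arg(denominator))
  (0.5 * rho_st * rho_uv * (rho_su^2 + rho_sv^2 + rho_tu^2 + rho_tv^2) +
      rho_su * rho_tv + rho_sv * rho_tu -
      (rho_st * rho_su * rho_sv + rho_st * rho_tu * rho_tv +
         rho_uv * rho_su * rho_tu + rho_uv * rho_sv * rho_tv)) / d
}

#' Fisher z transform and its sampling variance
#'
#' `r_to_z(r) = atanh(r)`; `z_variance(n) = 1 / (n - 3)`.
#'
#' @param r Correlation(s) strictly inside (-1, 1).
#' @return `r_to_z`: the z score(s); `z_to_r`: tanh back-transform;
#'   `z_variance`: the variance(s).
#' @export
r_to_z <- function(r) { .check_rho(r); atanh(r) }

#' @rdname r_to_z
#' @param z Fisher z score(s).
#' @export
z_to_r <- function(z) tanh(z)

#' @rdname r_to_z
#' @param n Sample size(s), >= 5.
#' @export
z_variance <- function(n) { .check_n(n); 1 / (n - 3) }

#' Build the block-diagonal Level-1 sampling covariance matrix
#'
#' Constructs one symmetric sampling-covariance block per sample from the
#' large-sample (co)variance formulas, using each sample's own observed
#' correlations as plug-in values. In `dependent` mode off-diagonal entries are
#' filled with the shared-variable / general covariance expressions; in
#' `independent` mode blocks are diagonal (sampling variances only). On the
#' `fisher_z` scale, variances are `1/(n-3)` and covariances are mapped by the
#' delta method, `cov_z = cov_r / ((1 - r_st^2)(1 - r_uv^2))`.
#'
#' A formula may require a correlation the sample did not report (possible
#' with incomplete matrices). The `plugin` policy then substitutes the
#' n-weighted mean of that cell across all samples that observed it
#' (`"weighted_mean"`, default) or zero (`"zero"`); every substitution is
#' recorded in the returned `log`. The `"pooled"` policy instead evaluates
#' every formula input — including the variances — at the n-weighted pooled
#' correlations, the classic remedy when per-sample plug-ins are too noisy or
#' when weights must not co-vary with the observed effects. Blocks whose smallest eigenvalue falls
#' below -1e-10 are repaired to the nearest positive-semidefinite matrix
#' preserving the diagonal (eigenvalue clipping, then diagonal rescaling) when
#' `psd_repair = TRUE`; repairs are logged.
#'
#' @param data A `cor_data` object.
#' @param mode `"dependent"` (default; full blocks) or `"independent"`
#'   (diagonal blocks).
#' @param scale `"raw"` (default) or `"fisher_z"`.
#' @param plugin Plug-in policy: `"weighted_mean"` or `"zero"` substitute
#'   only correlations a formula needs but the sample did not observe;
#'   `"pooled"` evaluates all formula inputs at the pooled correlations.
#' @param psd_repair Repair indefinite blocks (default `TRUE`).
#' @inheritParams cor_variance
#' @return Object of class `cor_vmat`: list with `blocks` (named by
#'   sample_id, row/col names are cell labels), `index` (the dataset's index
#'   frame), `scale`, `mode`, `denominator`, and `log` (tibble of plug-in
#'   substitutions and PSD repairs).
#' @export
build_vmat <- function(data, mode = c("dependent", "independent"),
                       scale = c("raw", "fisher_z"),
                       plugin = c("weighted_mean", "zero", "pooled"),
                       psd_repair = TRUE, denominator = c("n", "n-1")) {
  stopifnot(inherits(data, "cor_data"))
  mode <- match.arg(mode); scale <- match.arg(scale)
  plugin <- match.arg(plugin); denominator <- match.arg(denominator)
  vec <- cor_vectorize(data)
  idx <- vec$index

  # n-weighted mean per cell across samples, for the plug-in policy
  cellmeans <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$cell),
    wmean = sum(.data$r * .data$n) / sum(.data$n), .groups = "drop")
  wmean <- stats::setNames(cellmeans$wmean, cellmeans$cell)

  log_events <- list()
  blocks <- list()
  for (sid in unique(idx$sample_id)) {
    rows <- idx[idx$sample_id == sid, , drop = FALSE]
    sub <- data[data$sample_id == sid, , drop = FALSE]
    n_s <- rows$n[1]
    m <- nrow(rows)
    cells <- rows$cell
    # local correlation lookup: observed value, else plug-in
    vars_s <- unique(c(sub$var_a, sub$var_b))
    lookup <- function(a, b) {
      if (a == b) return(1)
      lbl <- cell_label_sorted(a, b, .vars_of(data))
      if (plugin == "pooled") {
        return(if (lbl %in% names(wmean)) wmean[[lbl]] else 0)
      }
      hit <- match(lbl, sub$cell)
      if (!is.na(hit)) return(sub$r[hit])
      val <- if (plugin == "weighted_mean" && lbl %in% names(wmean)) {
        wmean[[lbl]]
      } else 0
      log_events[[length(log_events) + 1]] <<- tibble::tibble(
        event = "plugin", sample_id = sid, cell = lbl, value = val)
      val
    }
    r_in <- if (plugin == "pooled") unname(wmean[sub$cell]) else sub$r
    B <- matrix(0, m, m, dimnames = list(cells, cells))
    for (i in seq_len(m)) {
      B[i, i] <- cor_variance(r_in[i], n_s, denominator)
      if (mode == "dependent" && i < m) {
        for (j in seq((i + 1), m)) {
          B[i, j] <- B[j, i] <-
            .pair_cov(sub$var_a[i], sub$var_b[i], sub$var_a[j], sub$var_b[j],
                      lookup, n_s, denominator)
        }
      }
    }
    if (scale == "fisher_z") {
      fac <- 1 / (1 - r_in^2)
      B <- B * tcrossprod(fac)
      diag(B) <- z_variance(n_s)
    }
    B <- (B + t(B)) / 2
    if (psd_repair && m > 1) {
      ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10) {
        B <- .psd_repair_block(B)
        log_events[[length(log_events) + 1]] <- tibble::tibble(
          event = "psd_repair", sample_id = sid, cell = NA_character_,
          value = min(ev))
      }
    }
    blocks[[sid]] <- B
  }
  structure(list(
    blocks = blocks, index = idx, scale = scale, mode = mode,
    denominator = denominator,
    log = if (length(log_events)) dplyr::bind_rows(log_events) else
      tibble::tibble(event = character(), sample_id = character(),
                     cell = character(), value = double())
  ), class = "cor_vmat")
}

# covariance between cells (a1,b1) and (a2,b2) given a correlation lookup
.pair_cov <- function(a1, b1, a2, b2, lookup, n, denominator) {
  shared <- intersect(c(a1, b1), c(a2, b2))
  if (length(shared) == 2) {
    return(cor_variance(lookup(a1, b1), n, denominator))
  }
  if (length(shared) == 1) {
    s <- shared
    t <- setdiff(c(a1, b1), s)
    u <- setdiff(c(a2, b2), s)
    return(cor_covariance_shared(lookup(t, u), lookup(s, t), lookup(s, u),
                                 n, denominator))
  }
  cor_covariance_general(lookup(a1, b1), lookup(a2, b2),
                         lookup(a1, a2), lookup(a1, b2),
                         lookup(b1, a2), lookup(b1, b2), n, denominator)
}

.psd_repair_block <- function(B, floor = 1e-10) {
  d <- diag(B)
  e <- eigen(B, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  R <- e$vectors %*% (lam * t(e$vectors))
  # restore the original sampling variances on the diagonal
  s <- sqrt(d / diag(R))
  R <- R * tcrossprod(s)
  (R + t(R)) / 2
}

#' @export
print.cor_vmat <- function(x, ...) {
  cat(sprintf("Sampling covariance matrix: %d blocks, %d rows, %s mode, %s scale\n",
              length(x$blocks), nrow(x$index), x$mode, x$scale))
  if (nrow(x$log) > 0) {
    cat(sprintf("  %d plug-in substitutions, %d PSD repairs logged\n",
                sum(x$log$event == "plugin"), sum(x$log$event == "psd_repair")))
  }
  invisible(x)
}

#' Assemble the full block-diagonal matrix
#'
#' @param x A `cor_vmat` object.
#' @param ... Unused.
#' @return Dense N x N matrix in dataset row order; entries across samples are
#'   structurally zero.
#' @export
as.matrix.cor_vmat <- function(x, ...) {
  N <- nrow(x$index)
  V <- matrix(0, N, N)
  for (sid in names(x$blocks)) {
    rows <- x$index$row[x$index$sample_id == sid]
    V[rows, rows] <- x$blocks[[sid]]
  }
  V
}

#' Export / import a sampling covariance matrix as sparse text
#'
#' The exchange format is a coordinate-format text file with 0-based `row`,
#' `col`, `value` triplets aligned to the dataset vectorization (upper triangle
#' included; the matrix is symmetric), plus a JSON sidecar recording block
#' boundaries, scale and mode.
#'
#' @param x A `cor_vmat` object.
#' @param path Output path for the triplet file; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly (for `write_vmat`); a `cor_vmat` for `read_vmat`.
#' @export
write_vmat <- function(x, path) {
  stopifnot(inherits(x, "cor_vmat"))
  trips <- purrr::map_dfr(names(x$blocks), function(sid) {
    rows <- x$index$row[x$index$sample_id == sid]
    B <- x$blocks[[sid]]
    ij <- which(B != 0 | row(B) == col(B), arr.ind = TRUE)
    tibble::tibble(row = rows[ij[, 1]] - 1L, col = rows[ij[, 2]] - 1L,
                   value = B[ij])
  })
  trips <- dplyr::arrange(trips, .data$row, .data$col)
  readr::write_csv(trips, path, progress = FALSE)
  sidecar <- list(
    scale = x$scale, mode = x$mode, denominator = x$denominator,
    n_rows = nrow(x$index),
    blocks = purrr::map(names(x$blocks), function(sid) {
      list(sample_id = sid,
           rows = x$index$row[x$index$sample_id == sid] - 1L)
    })
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vmat
#' @param data The `cor_data` object the matrix aligns to.
#' @export
read_vmat <- function(path, data) {
  stopifnot(inherits(data, "cor_data"))
  trips <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vec <- cor_vectorize(data)
  idx <- vec$index
  if (nrow(idx) != sidecar$n_rows) {
    stop("sampling covariance file does not match the dataset dimension",
         call. = FALSE)
  }
  V <- matrix(0, nrow(idx), nrow(idx))
  V[cbind(trips$row + 1L, trips$col + 1L)] <- trips$value
  V <- (V + t(V)) / 2  # both triangles are stored, so this is exact
  blocks <- list()
  for (sid in unique(idx$sample_id)) {
    rows <- idx$row[idx$sample_id == sid]
    B <- V[rows, rows, drop = FALSE]
    dimnames(B) <- list(idx$cell[rows], idx$cell[rows])
    blocks[[sid]] <- B
  }
  structure(list(blocks = blocks, index = idx, scale = sidecar$scale,
                 mode = sidecar$mode, denominator = sidecar$denominator,
                 log = tibble::tibble(event = character(),
                                      sample_id = character(),
                                      cell = character(), value = double())),
            class = "cor_vmat")
}

# canonical label for an unordered pair given the roster
cell_label_sorted <- function(a, b, variables) {
  ia <- match(a, variables); ib <- match(b, variables)
  if (ia <= ib) cell_label(a, b) else cell_label(b, a)
}

.check_rho <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    stop("correlations must be finite and strictly inside (-1, 1)",
         call. = FALSE)
  }
  invisible(TRUE)
}

.check_n <- function(n) {
  if (any(!is.finite(n)) || any(n < 5)) {
    stop("sample sizes must be >= 5", call. = FALSE)
  }
  invisible(TRUE)
}

.denom <- function(n, denominator) if (denominator == "n") n else n - 1
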