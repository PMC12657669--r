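#' Specify a multilevel multivariate working model
#'
#' A working model fixes the structure of the within-study (Level-2, `T`) and
#' between-study (Level-3, `Gamma`) random-effect covariance matrices over
#' cells, plus the fixed correlations among random effects and the analysis
#' scale. The four canonical models are:
#'
#' * Model 1: HCS within, HCS between — per-cell tau^2 and gamma^2 (2C
#'   variance parameters for C cells);
#' * Model 2: HCS within, CS between — per-cell tau^2, one shared gamma^2
#'   (C + 1);
#' * Model 3: CS within, HCS between — one shared tau^2, per-cell gamma^2
#'   (C + 1);
#' * Model 4: CS within, CS between — one tau^2, one gamma^2 (2).
#'
#' `DIAG` and `ID` are the zero-correlation special cases of `HCS` and `CS`.
#' The random-effect correlations `rho` (within) and `phi` (between) are fixed
#' constants in [0, 1], not estimated; 1 is allowed as a PSD boundary (the
#' sampling covariance keeps the marginal covariance positive definite).
#'
#' @param model Integer 1-4 selecting a canonical model, or `NULL` to give
#'   `within`/`between` directly.
#' @param within,between Structure strings `"HCS"`, `"CS"`, `"DIAG"`, `"ID"`.
#' @param rho Fixed correlation among within-study random effects, in [0, 1].
#' @param phi Fixed correlation among between-study random effects, in [0, 1].
#' @param scale `"raw"` (Pearson r) or `"fisher_z"` (analysis on atanh(r)).
#' @return Object of class `working_model`.
#' @examples
#' working_model(2)                        # HCS within, CS between, rho=phi=0
#' working_model(within = "DIAG", between = "ID")
#' @export
working_model <- function(model = NULL, within = NULL, between = NULL,
                          rho = 0, phi = 0, scale = c("raw", "fisher_z")) {
  scale <- match.arg(scale)
  if (!is.null(model)) {
    stopifnot(model %in% 1:4)
    structs <- list(`1` = c("HCS", "HCS"), `2` = c("HCS", "CS"),
                    `3` = c("CS", "HCS"), `4` = c("CS", "CS"))[[as.character(model)]]
    if (is.null(within)) within <- structs[1]
    if (is.null(between)) between <- structs[2]
  }
  within <- match.arg(within, c("HCS", "CS", "DIAG", "ID"))
  between <- match.arg(between, c("HCS", "CS", "DIAG", "ID"))
  if (within %in% c("DIAG", "ID")) rho <- 0
  if (between %in% c("DIAG", "ID")) phi <- 0
  stopifnot(rho >= 0, rho <= 1, phi >= 0, phi <= 1)
  model_id <- .model_id(within, between, rho, phi)
  structure(list(model_id = model_id, within = within, between = between,
                 rho = rho, phi = phi, scale = scale),
            class = "working_model")
}

.model_id <- function(within, between, rho, phi) {
  w <- if (within %in% c("HCS", "DIAG")) "H" else "C"
  b <- if (between %in% c("HCS", "DIAG")) "H" else "C"
  c(HH = 1L, HC = 2L, CH = 3L, CC = 4L)[[paste0(w, b)]]
}

#' @export
print.working_model <- function(x, ...) {
  cat(sprintf("Working model %d: within %s (rho = %g), between %s (phi = %g), %s scale\n",
              x$model_id, x$within, x$rho, x$between, x$phi, x$scale))
  invisible(x)
}

# number of free variance parameters per level
.n_varpar <- function(structure, C) {
  if (structure %in% c("HCS", "DIAG")) C else 1L
}

# C x C random-effect covariance from per-cell variances and a fixed correlation
.re_cov <- function(var2, cor, C) {
  v <- if (length(var2) == 1) rep(var2, C) else var2
  s <- sqrt(v)
  G <- tcrossprod(s) * cor
  diag(G) <- v
  G
}

# does `small` structure nest inside `big`? (CS/ID constrain HCS/DIAG; a zero
# fixed correlation is a different fixed constant, not a free parameter, so
# nesting additionally requires equal rho/phi, checked by the caller)
.nests_in <- function(small, big) {
  rank_of <- function(s) if (s %in% c("HCS", "DIAG")) 2L else 1L
  rank_of(small) <= rank_of(big)
}
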