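#' Diffusion acquisition scheme
#'
#' An acquisition scheme holds the per-measurement diffusion weighting
#' (b-value, in s/mm^2) and unit gradient direction, together with the
#' timing constants shared by all measurements of a pulsed-field-gradient
#' experiment: gradient duration `delta` (s), diffusion time `Delta` (s)
#' and the gyromagnetic ratio `gamma` (rad/s/T). The per-measurement
#' gradient amplitude `G` (T/m) is optional and, when present, must be
#' consistent with \eqn{b = (\gamma \delta G)^2 (\Delta - \delta/3)}
#' within 0.1%.
#'
#' @param b numeric vector of b-values, s/mm^2, all `>= 0`.
#' @param dirs n x 3 matrix of gradient directions; unit norm for
#'   diffusion-weighted measurements, zero rows allowed where `b = 0`.
#' @param delta gradient pulse duration, s.
#' @param Delta diffusion time, s; must exceed `delta`.
#' @param gamma gyromagnetic ratio, rad/s/T (default: proton).
#' @param G optional per-measurement gradient amplitude, T/m.
#' @return an object of class `acq_scheme`.
#' @seealso [make_scheme()] for the synthetic Cartesian-grid schemes.
#' @export
acq_scheme <- function(b, dirs, delta, Delta, gamma = 2.675e8, G = NULL) {
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3L) stop("dirs must be an n x 3 matrix")
  if (length(b) != nrow(dirs)) stop("length(b) must match nrow(dirs)")
  if (any(b < 0)) stop("all b-values must be >= 0")
  if (delta >= Delta) stop("delta must be smaller than Delta")
  nrm <- sqrt(rowSums(dirs^2))
  dw <- b > 0
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop("diffusion-weighted directions must have unit norm (tolerance 1e-6)")
  if (any(b[!dw] > 0)) stop("internal: inconsistent b partition")
  if (!is.null(G)) {
    if (length(G) != length(b)) stop("G must have one value per measurement")
    b_pred <- b_value_from_gradient(gamma, delta, G, Delta)
    rel <- abs(b_pred - b) / pmax(b, 1)
    if (any(rel > 1e-3))
      stop("b-values inconsistent with (gamma*delta*G)^2*(Delta - delta/3) ",
           "beyond 0.1%")
  }
  structure(list(b = as.numeric(b), dirs = dirs, delta = delta, Delta = Delta,
                 gamma = gamma, G = G, n_non_dw = sum(!dw)),
            class = "acq_scheme")
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat(sprintf(paste0("Acquisition scheme: %d measurements (%d non-DW), ",
                     "b in [0, %g] s/mm^2\n  delta = %g ms, Delta = %g ms\n"),
              length(x$b), x$n_non_dw, max(x$b),
              x$delta * 1e3, x$Delta * 1e3))
  invisible(x)
}

#' @export
length.acq_scheme <- function(x) length(x$b)

# scheme restricted to measurements with b <= b_max
subset_scheme <- function(scheme, b_max) {
  keep <- scheme$b <= b_max
  structure(list(b = scheme$b[keep], dirs = scheme$dirs[keep, , drop = FALSE],
                 delta = scheme$delta, Delta = scheme$Delta,
                 gamma = scheme$gamma, G = scheme$G[keep],
                 n_non_dw = sum(scheme$b[keep] == 0), keep = which(keep)),
            class = "acq_scheme")
}

#' b-value of a rectangular pulsed-field-gradient experiment
#'
#' \eqn{b = (\gamma \delta G)^2 (\Delta - \delta/3)}, evaluated in SI
#' units (s/m^2) and converted to the conventional s/mm^2 (factor 1e-6).
#'
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @param delta gradient duration, s.
#' @param G gradient amplitude, T/m (vectorised).
#' @param Delta diffusion time, s; must exceed `delta`.
#' @return b-value(s) in s/mm^2.
#' @examples
#' b_value_from_gradient(2.675e8, 5e-3, 1, 9e-3) # about 1.31e4 s/mm^2
#' @export
b_value_from_gradient <- function(gamma, delta, G, Delta) {
  stopifnot(gamma > 0, delta > 0, all(G >= 0))
  if (delta >= Delta) stop("delta must be smaller than Delta")
  (gamma * delta * G)^2 * (Delta - delta / 3) * 1e-6
}

# q-value (1/mm) corresponding to b (s/mm^2): b = 4 pi^2 q^2 (Delta - delta/3)
q_from_b <- function(b, delta, Delta) {
  sqrt(b / (4 * pi^2 * (Delta - delta / 3)))
}

#' Write / read an acquisition scheme as FSL-dialect bval/bvec + JSON sidecar
#'
#' `bval` is one space-separated row of b-values; `bvec` is three rows
#' (x, y, z components); the JSON sidecar stores `delta`, `Delta` and
#' `gamma`.
#'
#' @param scheme an [acq_scheme()].
#' @param stem path stem; writes `<stem>.bval`, `<stem>.bvec`,
#'   `<stem>.json`.
#' @return `write_scheme` returns `stem` invisibly; `read_scheme` returns
#'   an `acq_scheme`.
#' @export
write_scheme <- function(scheme, stem) {
  writeLines(paste(format(scheme$b, trim = TRUE), collapse = " "),
             paste0(stem, ".bval"))
  writeLines(apply(t(scheme$dirs), 1, paste, collapse = " "),
             paste0(stem, ".bvec"))
  jsonlite::write_json(list(delta = scheme$delta, Delta = scheme$Delta,
                            gamma = scheme$gamma),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(stem) {
  b <- scan(paste0(stem, ".bval"), quiet = TRUE)
  v <- do.call(rbind, lapply(readLines(paste0(stem, ".bvec")),
                             function(l) scan(text = l, quiet = TRUE)))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  acq_scheme(b, t(v), delta = side$delta, Delta = side$Delta,
             gamma = side$gamma)
}
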