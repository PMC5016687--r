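#' Solve the mass-balance equations of a binding scheme
#'
#' Finds the equilibrium free concentrations `x_j` satisfying, for every
#' component `j`,
#' \deqn{x_j + \sum_c \nu_{cj}\, [\mathrm{c}](x) = T_j, \qquad
#'       [\mathrm{c}](x) = \prod_j x_j^{\nu_{cj}} / K_c,}
#' by damped Newton iteration on `u = log x` (which keeps all
#' concentrations positive), initialised at `x = T`.  Components with zero
#' total are eliminated up front, together with every complex containing
#' them.  The iteration is deterministic for fixed inputs.
#'
#' @param scheme A [binding_scheme()].
#' @param rel_tol Relative mass-balance tolerance, in `(0, 1e-3]`; each
#'   component's balance must close within
#'   `rel_tol * max(total, conc_floor)`.  Default `1e-9`.
#' @param max_iter Iteration cap before declaring non-convergence.
#' @param conc_floor Concentration floor (M) making relative residuals
#'   well defined at zero totals.  Default `1e-30`.
#' @return An object of class `"speciation_result"`: list with `free`
#'   (named numeric, M), `complexed` (named numeric, M), `residual`
#'   (max relative mass-balance violation) and `iterations`.
#' @examples
#' s <- binding_scheme(
#'   components = list(component("P", 1e-7), component("D", 1e-8)),
#'   complexes  = list(complex_species("PD", c(P = 1, D = 1), 1e-7))
#' )
#' solve_speciation(s)$complexed[["PD"]]  # ~4.875e-9 M
#' @export
solve_speciation <- function(scheme, rel_tol = 1e-9, max_iter = 200L,
                             conc_floor = 1e-30) {
  stopifnot(inherits(scheme, "binding_scheme"))
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol > 1e-3) {
    stop("rel_tol must lie in (0, 1e-3]", call. = FALSE)
  }
  totals <- vapply(scheme$components, `[[`, numeric(1), "total")
  names(totals) <- vapply(scheme$components, `[[`, character(1), "name")
  if (any(!is.finite(totals)) || any(totals < 0)) {
    stop("component totals must be finite and >= 0", call. = FALSE)
  }
  nu <- scheme_matrix(scheme)
  ks <- vapply(scheme$complexes, `[[`, numeric(1), "k_overall")

  free <- stats::setNames(numeric(length(totals)), names(totals))
  complexed <- stats::setNames(numeric(nrow(nu)), rownames(nu))

  active <- totals > 0
  # complexes containing an absent component cannot form
  if (nrow(nu)) {
    cx_active <- apply(nu, 1L, function(row) all(active[row > 0]))
  } else {
    cx_active <- logical(0)
  }

  if (!any(active)) {
    return(structure(list(free = free, complexed = complexed,
                          residual = 0, iterations = 0L),
                     class = "speciation_result"))
  }

  Tj <- totals[active]
  nuA <- nu[cx_active, active, drop = FALSE]
  kA <- ks[cx_active]
  scale <- pmax(Tj, conc_floor)

  if (nrow(nuA) == 0L) {
    free[active] <- Tj
    return(structure(list(free = free, complexed = complexed,
                          residual = 0, iterations = 0L),
                     class = "speciation_result"))
  }

  res <- speciation_newton(Tj, nuA, kA, scale, rel_tol, max_iter)
  if (!res$converged) {
    worst <- names(Tj)[which.max(abs(res$f) / scale)]
    stop("speciation solver failed to converge within ", max_iter,
         " iterations; worst mass-balance residual on component '",
         worst, "' (", format(max(abs(res$f) / scale), digits = 3),
         " relative)", call. = FALSE)
  }
  free[active] <- res$x
  complexed[cx_active] <- res$cx
  structure(list(free = free, complexed = complexed,
                 residual = res$residual, iterations = res$iterations),
            class = "speciation_result")
}

# damped Newton on u = log x; Tj, scale: length-n; nuA: m x n; kA: length-m
speciation_newton <- function(Tj, nuA, kA, scale, rel_tol, max_iter,
                              x0 = NULL) {
  n <- length(Tj)
  x <- if (is.null(x0)) Tj else pmin(pmax(x0, 1e-300), Tj)
  u <- log(x)

  balance <- function(u) {
    x <- exp(u)
    cx <- exp(nuA %*% u - log(kA))  # column vector m x 1
    f <- x + drop(crossprod(nuA, cx)) - Tj
    list(x = x, cx = drop(cx), f = f)
  }

  st <- balance(u)
  best <- st
  for (it in seq_len(max_iter)) {
    rel <- max(abs(st$f) / scale)
    if (rel <= rel_tol) {
      return(list(converged = TRUE, x = st$x, cx = st$cx, f = st$f,
                  residual = rel, iterations = it - 1L))
    }
    # J_{jk} = d f_j / d u_k = delta_jk x_j + sum_c nu_cj nu_ck [c]
    J <- diag(st$x, n, n) + crossprod(nuA * sqrt(st$cx))
    step <- tryCatch(solve(J, st$f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- st$f / pmax(diag(J), 1e-300)  # Jacobi fallback
    }
    lambda <- 1
    f0 <- sum((st$f / scale)^2)
    repeat {
      u_try <- u - lambda * step
      u_try <- pmax(u_try, log(1e-300))
      st_try <- balance(u_try)
      if (all(is.finite(st_try$f)) &&
          sum((st_try$f / scale)^2) < f0) {
        u <- u_try
        st <- st_try
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-12) {  # stuck; accept and let outer loop decide
        u <- u_try
        st <- st_try
        break
      }
    }
  }
  rel <- max(abs(st$f) / scale)
  list(converged = rel <= rel_tol, x = st$x, cx = st$cx, f = st$f,
       residual = rel, iterations = max_iter)
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Speciation result (residual ", format(x$residual, digits = 3),
      ", ", x$iterations, " iterations)\n", sep = "")
  for (nm in names(x$free)) {
    cat(sprintf("  free %-8s %.6g M\n", nm, x$free[[nm]]))
  }
  for (nm in names(x$complexed)) {
    cat(sprintf("  [%s]%*s %.6g M\n", nm, max(0, 11 - nchar(nm)), "",
                x$complexed[[nm]]))
  }
  invisible(x)
}

#' Closed-form bound concentration for 1:1 binding
#'
#' Root of the binding quadratic `[PD]^2 - (P+D+K)[PD] + PD = 0` lying in
#' `[0, min(p_tot, d_tot)]`, evaluated in the numerically stable form.
#' Used as the independent oracle for the speciation solver on 1:1
#' schemes.
#'
#' @param k Dissociation constant (M, > 0).
#' @param p_tot,d_tot Totals of the two partners (M, >= 0).
#' @return Bound complex concentration (M).
#' @export
closed_form_single_site <- function(k, p_tot, d_tot) {
  if (!is.numeric(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (p_tot < 0 || d_tot < 0) stop("totals must be >= 0", call. = FALSE)
  s <- p_tot + d_tot + k
  disc <- s * s - 4 * p_tot * d_tot
  # stable root: subtractive cancellation avoided via the product form
  r <- (s - sqrt(max(disc, 0))) / 2
  min(max(r, 0), min(p_tot, d_tot))
}
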