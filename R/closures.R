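#' PSE-n / KH / HNC closure family
#'
#' Pair distribution from the renormalised indirect function
#' t* = -beta*u + h - c:
#' \deqn{g = exp(t*) \quad (t* < 0); \qquad
#'       g = \sum_{i=0}^{n} t*^i / i! \quad (t* \ge 0).}
#' Order n = 1 is the Kovalenko-Hirata (KH) closure; n = Inf restores the
#' hypernetted chain (HNC), g = exp(t*) everywhere.
#'
#' @param tstar numeric scalar, vector or array.
#' @param order closure order n >= 1, or Inf for HNC.
#' @return g with the shape of \code{tstar}.
#' @examples
#' closureG(0.5, 1)   # 1.5  (KH linear branch)
#' closureG(0.5, 3)   # 1 + 0.5 + 0.125 + 0.0208333
#' @export
closureG <- function(tstar, order) {
  if (is.infinite(order)) return(exp(pmin(tstar, 700)))
  if (order < 1) stop("closure order must be >= 1 (or Inf for HNC)")
  g <- exp(pmin(tstar, 0))
  pos <- tstar >= 0
  if (any(pos)) {
    tp <- tstar[pos]
    acc <- 1 + tp
    term <- tp
    if (order >= 2) for (i in 2:order) {
      term <- term * tp / i
      acc <- acc + term
    }
    g[pos] <- acc
  }
  g
}

#' Derivative of the closure, dg/dt*
#'
#' Needed by the linearised (analytic) temperature-derivative solver:
#' dg/dt* = exp(t*) on the negative branch and the order-(n-1) partial sum
#' on the non-negative branch.
#'
#' @inheritParams closureG
#' @export
closureGPrime <- function(tstar, order) {
  if (is.infinite(order)) return(exp(pmin(tstar, 700)))
  g <- exp(pmin(tstar, 0))
  pos <- tstar >= 0
  if (any(pos)) {
    tp <- tstar[pos]
    acc <- rep(1, length(tp))
    term <- rep(1, length(tp))
    if (order >= 2) for (i in 1:(order - 1)) {
      term <- term * tp / i
      acc <- acc + term
    }
    g[pos] <- acc
  }
  g
}

.closureOrder <- function(closure) {
  if (is.numeric(closure)) return(closure)
  cl <- tolower(closure)
  if (cl == "kh") return(1)
  if (cl == "hnc") return(Inf)
  m <- regmatches(cl, regexec("^pse-?([0-9]+)$", cl))[[1]]
  if (length(m) == 2) return(as.numeric(m[2]))
  stop("unknown closure: ", closure)
}

.closureName <- function(order) {
  if (is.infinite(order)) "hnc"
  else if (order == 1) "kh"
  else paste0("pse", order)
}
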