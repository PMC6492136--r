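# Single-step transport operations exposed at the R level. The compiled
# kernel draws from the same laws with its own per-photon substreams; these
# surfaces exist for interactive exploration and distribution tests.

#' Sample free geometric path lengths
#'
#' Free paths between interactions are exponential with rate
#' `mu_t = mu_a + mu_s`: `-log(u)/mu_t` for `u ~ Uniform(0, 1]`.
#'
#' @param n number of draws.
#' @param layer a [tissue_layer()] row (or any list with `mu_s`, `mu_a`).
#' @param u optional uniform deviates (for deterministic checks).
#' @return path lengths (mm). For a non-scattering, non-absorbing layer
#'   (`mu_t = 0`) the free path is infinite: the packet steps to the next
#'   boundary instead.
#' @export
sample_free_path <- function(n, layer, u = NULL) {
  mu_t <- layer$mu_s + layer$mu_a
  if (mu_t <= 0) return(rep(Inf, n))
  if (is.null(u)) u <- stats::runif(n)
  -log(u) / mu_t
}

#' Deposit the absorbed weight fraction at an interaction
#'
#' Reduces the packet weight by `mu_a/(mu_a + mu_s)` of itself; the
#' deposited share is what a fluence tally would accumulate.
#'
#' @param weight packet weight(s).
#' @param layer a [tissue_layer()] row.
#' @return list with `weight` (surviving) and `deposited`.
#' @export
deposit_absorption <- function(weight, layer) {
  mu_t <- layer$mu_s + layer$mu_a
  if (mu_t <= 0) return(list(weight = weight, deposited = 0 * weight))
  dep <- weight * layer$mu_a / mu_t
  list(weight = weight - dep, deposited = dep)
}

#' Russian roulette for low-weight packets
#'
#' Packets below the weight threshold survive with probability `p_survive`
#' and have their weight multiplied by `1/p_survive`, so the expected
#' weight is conserved. Packets at or above the threshold are untouched.
#'
#' @param weight packet weight(s).
#' @param threshold roulette threshold.
#' @param p_survive survival probability in (0, 1].
#' @param u optional uniform deviates.
#' @return list with `weight` (0 for killed packets) and `alive` flags.
#' @export
roulette <- function(weight, threshold = 1e-4, p_survive = 0.1, u = NULL) {
  if (is.null(u)) u <- stats::runif(length(weight))
  eligible <- weight < threshold
  survive <- !eligible | (u < p_survive)
  out <- ifelse(eligible & survive, weight / p_survive,
                ifelse(survive, weight, 0))
  list(weight = out, alive = survive)
}
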