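#' Akaike weights for multi-model inference
#'
#' `w_i = exp(-dAIC_i / 2) / sum_k exp(-dAIC_k / 2)` with dAIC relative to
#' the smallest AIC. Invariant under adding a constant to every AIC; ties
#' give equal weights.
#'
#' @param aics Numeric vector of AIC values (at least one).
#' @return Weights summing to 1.
#' @export
aic_weights <- function(aics) {
  if (length(aics) == 0) abort("need at least one model AIC")
  w <- exp(-(aics - min(aics)) / 2)
  w / sum(w)
}

#' Allocate Monte Carlo realizations to models
#'
#' Stratified allocation: integer counts proportional to the weights using
#' largest-remainder rounding, summing exactly to `n`. Two models with
#' weights 0.6/0.4 at 10,000 iterations receive 6000 and 4000 realizations.
#'
#' @param weights Non-negative weights summing to 1.
#' @param n Total number of iterations (>= 1).
#' @return Integer vector of counts summing to `n`.
#' @export
allocate_realizations <- function(weights, n) {
  if (n < 1) abort("n must be >= 1")
  if (abs(sum(weights) - 1) > 1e-8) abort("weights must sum to 1")
  exact <- weights * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_idx <- order(exact - counts, decreasing = TRUE)
    counts[order_idx[seq_len(rem)]] <- counts[order_idx[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Construct a hierarchical model-weight tree
#'
#' A weight tree has one or more branches with fixed weights (for instance
#' the 50/50 split between sex-specific and joint attained-age models used
#' for some cancer groups); each branch holds a set of model ids whose
#' within-branch weights derive from their AIC values via [aic_weights()].
#'
#' @param branches List of branches, each a list with `weight` (fixed branch
#'   weight), `model_ids` (character) and `aics` (numeric, same length).
#'   A single branch with weight 1 expresses plain AIC weighting.
#' @return Object of class `weight_tree` with a flattened `leaves` tibble of
#'   per-model product weights.
#' @export
weight_tree <- function(branches) {
  bw <- map_dbl(branches, "weight")
  if (any(bw < 0) || abs(sum(bw) - 1) > 1e-12) {
    abort("branch weights must be non-negative and sum to 1")
  }
  leaves <- purrr::map_dfr(seq_along(branches), function(i) {
    br <- branches[[i]]
    if (length(br$model_ids) != length(br$aics)) {
      abort("model_ids and aics must have the same length")
    }
    w <- aic_weights(br$aics)
    tibble(branch = i, model_id = br$model_ids, branch_weight = br$weight,
           leaf_weight = w, weight = br$weight * w)
  })
  if (abs(sum(leaves$weight) - 1) > 1e-12) abort("leaf weights do not sum to 1")
  structure(list(branches = branches, leaves = leaves), class = "weight_tree")
}

#' Randomly select a model from a weight tree
#'
#' Draws a branch by its fixed weight, then a leaf by its AIC weight; the
#' selection frequencies converge to the product weights.
#'
#' @param tree A [weight_tree()].
#' @param n Number of draws.
#' @return Character vector of model ids.
#' @export
select_model <- function(tree, n = 1) {
  lv <- tree$leaves
  lv$model_id[sample.int(nrow(lv), size = n, replace = TRUE, prob = lv$weight)]
}

#' Assign models to iterations
#'
#' In `"stratified"` mode (default) the flattened product weights are turned
#' into exact per-model counts by largest-remainder rounding and the
#' iteration order is a seeded permutation; in `"random"` mode each
#' iteration draws its model independently via [select_model()].
#'
#' @param tree A [weight_tree()].
#' @param n Number of iterations.
#' @param mode `"stratified"` or `"random"`.
#' @return Character vector of length `n` of model ids.
#' @export
assign_models <- function(tree, n, mode = c("stratified", "random")) {
  mode <- match.arg(mode)
  if (mode == "random") return(select_model(tree, n))
  counts <- allocate_realizations(tree$leaves$weight, n)
  ids <- rep(tree$leaves$model_id, counts)
  sample(ids)
}
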