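# Exact computation of P(h^v) and the match-count distribution on small
# pedigrees: by bounded exhaustive enumeration, and by a sum-product dynamic
# program over the suspect-rooted tree. Either serves as ground truth for the
# importance-sampling estimators.
#
# Support bound: under the single-step model a member at depth d below the
# suspect can differ from the suspect haplotype by at most d repeats per
# marker, so enumeration over the box [-d, d] per marker is exhaustive.

# per-untyped-member allele ranges (list over members of list over markers)
support_ranges <- function(prep) {
  lapply(prep$order, function(id) {
    d <- prep$depth[[id]]
    lapply(seq_along(prep$panel), function(j) seq.int(-d, d))
  })
}

oracle_result <- function(pv, probs, method) {
  list(pv = pv,
       dist = new_match_distribution(probs, exact = TRUE),
       method = method)
}

#' Exact match distribution by exhaustive enumeration
#'
#' Sums the product of edge transition probabilities over every assignment of
#' untyped haplotypes within the support bound. P(h^v) is the total mass;
#' p_x is the mass restricted to assignments with exactly x untyped members
#' carrying the suspect haplotype, divided by P(h^v). The per-x probabilities
#' sum to one exactly.
#'
#' @param case a [case_configuration()].
#' @param model a [mutation_model()].
#' @param cap refuse enumerations larger than this many joint states.
#' @return list with `pv`, `dist` (exact `ystr_match_distribution` over
#'   x = 0..n-k) and `method = "enum"`.
#' @export
exact_distribution_enum <- function(case, model, cap = 2e6) {
  prep <- prepare_case(case)
  check_panel(prep, model)
  U <- length(prep$order)
  L <- length(prep$panel)

  if (U == 0) {
    pv <- exact_pv_no_untyped(prep, model)
    if (pv == 0) stop_undefined_pv()
    return(oracle_result(pv, c(`0` = 1), "enum"))
  }

  ranges <- unlist(support_ranges(prep), recursive = FALSE)
  n_states <- prod(vapply(ranges, length, numeric(1)))
  if (n_states > cap)
    stop_cap("enumeration needs ", format(n_states, big.mark = ","),
             " states, above the cap of ", format(cap, big.mark = ","),
             "; use the importance-sampling estimator instead")
  grid <- as.matrix(do.call(expand.grid, ranges))
  colnames(grid) <- paste(rep(prep$order, each = L), rep(seq_len(L), U), sep = ".")

  value_col <- function(id, j) {
    # allele values of member `id`, marker j, across all enumeration states
    if (!is.null(prep$typed_shifted[[id]]))
      rep(prep$typed_shifted[[id]][[j]], nrow(grid))
    else grid[, paste(id, j, sep = ".")]
  }
  w <- rep(1, nrow(grid))
  for (son in setdiff(prep$pedigree$members, prep$pedigree$root)) {
    fa <- prep$pedigree$father[[son]]
    for (j in seq_len(L))
      w <- w * step_factor(value_col(son, j) - value_col(fa, j), prep_rate(model, j))
  }
  pv <- sum(w)
  if (pv == 0) stop_undefined_pv()
  match_count <- rep(0L, nrow(grid))
  for (id in prep$order) {
    is_match <- rep(TRUE, nrow(grid))
    for (j in seq_len(L)) is_match <- is_match & value_col(id, j) == 0L
    match_count <- match_count + is_match
  }
  mass <- vapply(0:U, function(x) sum(w[match_count == x]), numeric(1))
  oracle_result(pv, stats::setNames(mass / pv, 0:U), "enum")
}

exact_pv_no_untyped <- function(prep, model) {
  pv <- 1
  for (son in setdiff(prep$pedigree$members, prep$pedigree$root)) {
    fa <- prep$pedigree$father[[son]]
    pv <- pv * transition_prob(prep$typed_shifted[[fa]],
                               prep$typed_shifted[[son]], model)
  }
  pv
}

stop_undefined_pv <- function() {
  stop(errorCondition(
    "P(h^v) = 0 under the single-step model: the conditional match distribution is undefined",
    class = c("ystr_undefined_conditional", "error")))
}

#' Exact match distribution by sum-product dynamic programming
#'
#' Bottom-up pass over the suspect-rooted tree. Every node carries a table
#' over (own haplotype state, match count among untyped members of its
#' subtree); children are absorbed by a transition-weighted matrix product
#' and a convolution over match counts. Typed nodes contribute a point mass
#' at their observed haplotype; the root (the suspect, pinned to his own
#' haplotype) yields the joint masses P(h^v, m = x), from which
#' P(h^v) = sum_x and p_x = joint / P(h^v). Agrees with
#' [exact_distribution_enum()] to full double precision but scales with the
#' tree size instead of the joint state space.
#'
#' @inheritParams exact_distribution_enum
#' @param cap refuse per-node state spaces larger than this.
#' @return list with `pv`, `dist` and `method = "dp"`.
#' @export
exact_distribution_dp <- function(case, model, cap = 2e6) {
  prep <- prepare_case(case)
  check_panel(prep, model)
  U <- length(prep$order)
  L <- length(prep$panel)
  if (U == 0) {
    pv <- exact_pv_no_untyped(prep, model)
    if (pv == 0) stop_undefined_pv()
    return(oracle_result(pv, c(`0` = 1), "dp"))
  }
  children <- pedigree_children(prep$pedigree)

  # state grid of a node: typed -> its observed haplotype; untyped -> the
  # support box around the suspect haplotype
  node_states <- function(id) {
    if (!is.null(prep$typed_shifted[[id]]))
      return(matrix(prep$typed_shifted[[id]], nrow = 1L))
    d <- prep$depth[[id]]
    if ((2 * d + 1)^L > cap)
      stop_cap("per-node state space (", (2 * d + 1)^L,
               ") above the cap of ", cap)
    as.matrix(do.call(expand.grid, rep(list(seq.int(-d, d)), L)))
  }

  # transition matrix between two state grids (rows: parent, cols: child)
  trans_matrix <- function(ps, cs) {
    out <- matrix(1, nrow(ps), nrow(cs))
    for (j in seq_len(L))
      out <- out * step_factor(outer(ps[, j], cs[, j], `-`), prep_rate(model, j))
    out
  }

  convolve_counts <- function(a, b) {
    # rowwise convolution of two (states x counts) tables, truncated at U+1
    out <- matrix(0, nrow(a), U + 1L)
    for (i in seq_len(ncol(a))) {
      if (all(a[, i] == 0)) next
      jmax <- min(ncol(b), U + 2L - i)
      for (j in seq_len(jmax))
        out[, i + j - 1L] <- out[, i + j - 1L] + a[, i] * b[, j]
    }
    out
  }

  # W[s, m+1] = P(observations and m untyped matches in the subtree | state s)
  node_table <- function(id, states) {
    untyped_here <- is.null(prep$typed_shifted[[id]])
    W <- matrix(0, nrow(states), U + 1L)
    if (untyped_here) {
      m0 <- as.integer(rowSums(states != 0L) == 0L)  # own match indicator
      W[cbind(seq_len(nrow(states)), m0 + 1L)] <- 1
    } else W[, 1L] <- 1
    for (ch in children[[id]]) {
      cs <- node_states(ch)
      M <- trans_matrix(states, cs) %*% node_table(ch, cs)  # states x counts
      W <- convolve_counts(W, M)
    }
    W
  }

  root_states <- matrix(0L, nrow = 1L, ncol = L)  # suspect pinned to origin
  joint <- node_table(prep$pedigree$root, root_states)[1L, ]
  pv <- sum(joint)
  if (pv == 0) stop_undefined_pv()
  oracle_result(pv, stats::setNames(joint / pv, 0:U), "dp")
}
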