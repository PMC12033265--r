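#' Re-root a pedigree at the suspect
#'
#' Inverts the father-son relationships along the lineage between the suspect
#' and the current root (MRCA), so that the suspect becomes the new root. All
#' other edges are unchanged; the undirected edge set is preserved. The
#' manoeuvre is probabilistically neutral because the single-step mutation
#' model is symmetric.
#'
#' @param ped a [pedigree()].
#' @param suspect member id to place at the root.
#' @return a [pedigree()] rooted at `suspect`.
#' @export
reroot_at_suspect <- function(ped, suspect) {
  stopifnot(inherits(ped, "ystr_pedigree"))
  if (!suspect %in% ped$members)
    stop_validation("suspect `", suspect, "` is not a pedigree member")
  if (identical(suspect, ped$root)) return(ped)
  # path suspect -> ... -> root
  path <- suspect
  while (!is.na(ped$father[[path[length(path)]]]))
    path <- c(path, ped$father[[path[length(path)]]])
  fmap <- ped$father
  fmap[[suspect]] <- NA_character_
  for (i in seq_len(length(path) - 1L)) fmap[[path[i + 1L]]] <- path[i]
  out <- ped
  out$father <- fmap
  out$root <- suspect
  validate_pedigree(out, "re-rooted pedigree")
  out
}

#' Renumber a suspect-rooted pedigree by generation
#'
#' Assigns the integer ids used by the estimators: 1 for the suspect, 2..k for
#' the other typed members and k+1..n for the untyped members. Within each
#' group the numbering is non-decreasing in generation depth; ties within a
#' generation are broken lexicographically on the original member id (a
#' documented, deterministic choice that all probabilities are invariant to).
#' The processing `order` is the level-order traversal of the untyped members:
#' sons of the suspect first, then their sons, and so forth, which guarantees
#' that every untyped member is simulated after his father.
#'
#' @param ped a [pedigree()] rooted at the suspect.
#' @param typed_ids character vector of typed member ids (including the root).
#' @return object of class `ystr_rerooted` with fields `pedigree`, `numbering`
#'   (named integer vector), `order` (untyped ids in processing order) and
#'   `typed` (typed ids ordered by their numbers).
#' @export
renumber <- function(ped, typed_ids) {
  stopifnot(inherits(ped, "ystr_pedigree"))
  if (!ped$root %in% typed_ids)
    stop_validation("the root of a re-rooted pedigree must be the (typed) suspect")
  depth <- pedigree_depths(ped)
  by_group <- function(ids) ids[order(depth[ids], ids, method = "radix")]
  typed_others <- by_group(setdiff(typed_ids, ped$root))
  untyped <- by_group(setdiff(ped$members, typed_ids))
  numbering <- stats::setNames(
    seq_len(length(ped$members)),
    c(ped$root, typed_others, untyped))
  structure(list(pedigree = ped,
                 numbering = numbering,
                 order = untyped,
                 typed = c(ped$root, typed_others)),
            class = "ystr_rerooted")
}

# Full preparation of a case for the estimators and the oracle: re-root at the
# suspect, renumber, and shift all alleles so the suspect's haplotype is the
# origin at every marker (the shift is neutral under the shift-invariant
# single-step model and keeps the enumeration support centred).
prepare_case <- function(case) {
  if (inherits(case, "ystr_prepared")) return(case)
  stopifnot(inherits(case, "ystr_case"))
  rooted <- reroot_at_suspect(case$pedigree, case$suspect)
  rr <- renumber(rooted, names(case$typed))
  origin <- case$typed[[case$suspect]]
  typed_shifted <- lapply(case$typed, function(h) as.integer(h - origin))
  structure(list(case = case,
                 pedigree = rooted,
                 numbering = rr$numbering,
                 order = rr$order,
                 typed_ids = rr$typed,
                 typed_shifted = typed_shifted,
                 depth = pedigree_depths(rooted),
                 suspect = case$suspect,
                 panel = case$panel,
                 n = case$n, k = case$k),
            class = "ystr_prepared")
}
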