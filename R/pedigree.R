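#' Construct a patrilineal pedigree
#'
#' A pedigree is a rooted tree of patrilineally related males: every member
#' except the root (the most recent common ancestor, MRCA) has exactly one
#' father. Member ids are opaque strings; optional display labels may be
#' attached but identity is the id alone.
#'
#' @param father named character vector mapping each non-root member id to
#'   the id of his father. Names are the sons, values the fathers.
#' @param root id of the root member (the MRCA). If missing it is inferred as
#'   the unique father that is not himself a son.
#' @param labels optional named character vector of display labels.
#' @return an object of class `ystr_pedigree` with fields `members`, `father`
#'   (named vector, `NA` for the root), `root` and `labels`.
#' @examples
#' ped <- pedigree(c(son = "dad", dad = "grandpa"))
#' ped$root
#' @export
pedigree <- function(father, root = NULL, labels = NULL) {
  father <- as.character(father) |> stats::setNames(names(father))
  if (length(father) > 0 && (is.null(names(father)) || any(names(father) == "")))
    stop_validation("`father` must be a named vector (names = sons)")
  members <- unique(c(names(father), father, root))
  members <- members[!is.na(members)]
  if (is.null(root)) {
    cand <- setdiff(members, names(father))
    if (length(cand) != 1L)
      stop_validation("cannot infer root: found ", length(cand),
                      " members without a father (", paste(cand, collapse = ", "), ")")
    root <- cand
  }
  fmap <- stats::setNames(rep(NA_character_, length(members)), members)
  fmap[names(father)] <- father
  ped <- structure(
    list(members = members, father = fmap, root = root,
         labels = labels %||% stats::setNames(character(0), character(0))),
    class = "ystr_pedigree")
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped, where = "pedigree") {
  members <- ped$members
  fmap <- ped$father
  if (length(members) < 1L) stop_validation(where, ": no members")
  if (anyDuplicated(members)) {
    dup <- unique(members[duplicated(members)])
    stop_validation(where, ": duplicate member id(s): ", paste(dup, collapse = ", "))
  }
  roots <- members[is.na(fmap[members])]
  if (length(roots) != 1L)
    stop_validation(where, ": expected exactly one member without a father, found ",
                    length(roots), " (", paste(roots, collapse = ", "), ")")
  if (!identical(ped$root, roots)) stop_validation(where, ": root field does not match structure")
  bad <- setdiff(fmap[!is.na(fmap)], members)
  if (length(bad) > 0)
    stop_validation(where, ": father id(s) not in member set: ", paste(bad, collapse = ", "))
  # connectivity: every member must reach the root by following fathers;
  # a failure implies a cycle (the father relation allows no other defect here)
  reached <- pedigree_depths(ped)
  unreachable <- members[is.na(reached[members])]
  if (length(unreachable) > 0)
    stop_validation(where, ": cycle detected, member(s) not connected to the root: ",
                    paste(unreachable, collapse = ", "))
  invisible(ped)
}

# depth of each member below the root (root = 0); NA when the root is never
# reached (cycle / disconnected fragment)
pedigree_depths <- function(ped) {
  d <- stats::setNames(rep(NA_real_, length(ped$members)), ped$members)
  d[ped$root] <- 0
  ch <- pedigree_children(ped)
  queue <- ped$root
  while (length(queue) > 0) {
    v <- queue[[1L]]; queue <- queue[-1L]
    kids <- ch[[v]]
    if (!is.null(kids)) {
      d[kids] <- d[[v]] + 1
      queue <- c(queue, kids)
    }
  }
  d
}

# named list: member id -> character vector of sons (lexicographic)
pedigree_children <- function(ped) {
  sons <- names(ped$father)[!is.na(ped$father)]
  if (length(sons) == 0) return(list())
  out <- split(sons, ped$father[sons])
  lapply(out, function(v) v[lex_order(v)])
}

pedigree_edges <- function(ped) {
  sons <- ped$members[!is.na(ped$father[ped$members])]
  data.frame(father = unname(ped$father[sons]), son = sons,
             stringsAsFactors = FALSE)
}

#' @export
print.ystr_pedigree <- function(x, ...) {
  cat("Patrilineal pedigree: ", length(x$members), " members, root (MRCA) = ",
      x$root, "\n", sep = "")
  invisible(x)
}

#' Read a pedigree from Trivial Graph Format (TGF)
#'
#' The TGF dialect understood here is: one node per line (`id` optionally
#' followed by a label), a single line containing `#`, then one edge per line
#' (`father son`). Tokens are whitespace-separated. The separator line is
#' mandatory even when there are no edges. Edge direction is father to son;
#' the unique node with no father is the root (MRCA).
#'
#' @param file path to a TGF file, or a connection.
#' @return a validated [pedigree()].
#' @export
read_tgf <- function(file) {
  lines <- readLines(file, warn = FALSE)
  src <- if (is.character(file)) file else "TGF input"
  sep <- which(trimws(lines) == "#")
  if (length(sep) == 0)
    stop_parse(src, ": missing `#` separator line between nodes and edges")
  sep <- sep[[1L]]
  node_lines <- lines[seq_len(sep - 1L)]
  edge_lines <- if (sep < length(lines)) lines[(sep + 1L):length(lines)] else character(0)

  ids <- character(0); labels <- character(0)
  for (i in seq_along(node_lines)) {
    ln <- trimws(node_lines[[i]])
    if (ln == "") next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[[1L]] %in% ids)
      stop_parse(src, " line ", i, ": duplicate node id `", tok[[1L]], "`")
    ids <- c(ids, tok[[1L]])
    labels[tok[[1L]]] <- if (length(tok) > 1L) paste(tok[-1L], collapse = " ") else tok[[1L]]
  }
  if (length(ids) == 0) stop_parse(src, ": no nodes before the `#` separator")

  father <- stats::setNames(character(0), character(0))
  for (i in seq_along(edge_lines)) {
    ln <- trimws(edge_lines[[i]])
    if (ln == "") next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) < 2L)
      stop_parse(src, " line ", sep + i, ": edge line needs `father son`, got `", ln, "`")
    fa <- tok[[1L]]; so <- tok[[2L]]
    for (v in c(fa, so)) if (!v %in% ids)
      stop_parse(src, " line ", sep + i, ": edge references unknown node `", v, "`")
    if (so %in% names(father))
      stop_parse(src, " line ", sep + i, ": node `", so, "` has two fathers (`",
                 father[[so]], "`, `", fa, "`)")
    father[so] <- fa
  }

  roots <- setdiff(ids, names(father))
  if (length(roots) == 0)
    stop_parse(src, ": no root node (cycle covers every node)")
  if (length(roots) > 1L)
    stop_parse(src, ": disconnected pedigree, ", length(roots),
               " nodes without a father: ", paste(roots, collapse = ", "))
  ped <- tryCatch(
    pedigree(father, root = roots, labels = labels),
    ystr_validation_error = function(e) stop_parse(src, ": ", conditionMessage(e)))
  # preserve file order of members
  ped$members <- ids
  ped$father <- ped$father[ids]
  ped
}

#' Write a pedigree to Trivial Graph Format
#'
#' Inverse of [read_tgf()]: re-reading the output yields an identical
#' structure (member set, father map, root).
#'
#' @param ped a [pedigree()].
#' @param file path or connection to write to.
#' @export
write_tgf <- function(ped, file) {
  nodes <- vapply(ped$members, function(id) {
    lbl <- ped$labels[id]
    if (!is.na(lbl) && nzchar(lbl) && !identical(unname(lbl), id)) paste(id, lbl) else id
  }, character(1))
  e <- pedigree_edges(ped)
  writeLines(c(nodes, "#", if (nrow(e)) paste(e$father, e$son)), file)
  invisible(ped)
}

#' Read typed haplotypes from CSV
#'
#' The file must have a header `id,<marker>,<marker>,...`; each body row gives
#' a member id followed by integer repeat counts, one per marker. Fractional
#' alleles (e.g. `13.2`) and multi-copy markers are not supported by the
#' single-step mutation model and are rejected.
#'
#' @param file path to the CSV file.
#' @param panel character vector of marker names; the returned haplotypes
#'   follow this order. Defaults to the column order of the file.
#' @return named list mapping member id to an integer vector of repeat counts.
#' @export
read_haplotypes_csv <- function(file, panel = NULL) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  src <- if (is.character(file)) file else "haplotype CSV"
  if (ncol(df) < 2L || names(df)[[1L]] != "id")
    stop_parse(src, ": header must be `id` followed by marker names")
  markers <- names(df)[-1L]
  if (is.null(panel)) panel <- markers
  if (!setequal(markers, panel) || length(markers) != length(panel))
    stop_parse(src, ": marker columns (", paste(markers, collapse = ", "),
               ") do not match the panel (", paste(panel, collapse = ", "), ")")
  if (anyDuplicated(df$id))
    stop_parse(src, ": duplicate member id(s): ",
               paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  out <- list()
  for (r in seq_len(nrow(df))) {
    vals <- as.character(df[r, panel])
    bad <- !grepl("^-?[0-9]+$", vals)
    if (any(bad))
      stop_parse(src, " row ", r, " (id ", df$id[[r]], "): allele `",
                 vals[bad][[1L]], "` is not an integer repeat count ",
                 "(fractional and multi-copy alleles are not supported)")
    out[[df$id[[r]]]] <- stats::setNames(as.integer(vals), panel)
  }
  out
}

#' Assemble and check a case configuration
#'
#' Bundles the pedigree, the suspect id and the typed haplotypes. The suspect
#' must be typed; every typed member must belong to the pedigree.
#'
#' @param pedigree a [pedigree()].
#' @param suspect member id of the suspect.
#' @param typed named list of integer haplotypes (from [read_haplotypes_csv()]).
#' @param panel marker names; defaults to the names of the first haplotype.
#' @return an object of class `ystr_case` with fields `pedigree`, `suspect`,
#'   `typed`, `panel`, `n` (pedigree size) and `k` (number of typed members).
#' @export
case_configuration <- function(pedigree, suspect, typed, panel = NULL) {
  if (is.null(panel)) panel <- names(typed[[1L]]) %||% paste0("M", seq_along(typed[[1L]]))
  if (!suspect %in% names(typed))
    stop_validation("suspect `", suspect, "` has no typed haplotype")
  missing <- setdiff(names(typed), pedigree$members)
  if (length(missing) > 0)
    stop_validation("typed member(s) not in the pedigree: ",
                    paste(missing, collapse = ", "))
  typed <- lapply(typed, function(h) {
    if (length(h) != length(panel))
      stop_validation("haplotype length ", length(h),
                      " does not match panel size ", length(panel))
    stats::setNames(as.integer(h), panel)
  })
  structure(list(pedigree = pedigree, suspect = suspect, typed = typed,
                 panel = panel, n = length(pedigree$members), k = length(typed)),
            class = "ystr_case")
}

#' @export
print.ystr_case <- function(x, ...) {
  cat("Y-STR case: n = ", x$n, " members, k = ", x$k, " typed, suspect = ",
      x$suspect, ", panel = ", paste(x$panel, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a case against a mutation model
#'
#' Confirms the case invariants and flags typed father-son pairs whose
#' haplotypes differ by two or more repeats at any marker. Under the
#' single-step model such an edge has transition probability zero, which
#' forces P(h^v) = 0 and leaves the match distribution undefined.
#'
#' @param case a [case_configuration()].
#' @param model a [mutation_model()].
#' @return character vector of warning messages (empty when clean).
#' @export
validate_case <- function(case, model) {
  stopifnot(inherits(case, "ystr_case"), inherits(model, "ystr_mutation_model"))
  if (!setequal(case$panel, model$markers))
    stop_validation("case panel and mutation-model markers differ")
  warnings <- character(0)
  fmap <- case$pedigree$father
  for (son in names(case$typed)) {
    fa <- fmap[[son]]
    if (is.na(fa) || !fa %in% names(case$typed)) next
    delta <- abs(case$typed[[son]] - case$typed[[fa]])
    if (any(delta >= 2L))
      warnings <- c(warnings, paste0(
        "typed father-son pair (", fa, ", ", son, ") differs by >= 2 repeats at ",
        paste(case$panel[delta >= 2L], collapse = ", "),
        ": impossible under the single-step model, P(h^v) = 0"))
  }
  warnings
}
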