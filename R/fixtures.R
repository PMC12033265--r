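# Catalogue of the nine elementary validation pedigrees (A-I) with their
# allele assignments and closed-form results as polynomials in
# z = mu/2, the unidirectional mutation rate. Members are numbered in the
# renumbering convention: 1 = suspect (root), 2..k = other typed members by
# generation, k+1..n = untyped members by generation.
#
# Pedigree structures (edges father -> son):
#   A: 1->2                      (one untyped son)
#   B: 1->2->3                   (untyped chain of length two)
#   C: 1->2->3, member 2 typed   (typed son, untyped grandson)
#   D: 1->3->2                   (untyped son, typed grandson)
#   E: 1->3->4->2                (two untyped links, typed great-grandson)
#   F: 1->2; 2->3,4,5            (typed son with three untyped sons)
#   G: 1->5; 5->2,3,4            (untyped son with three typed sons)
#   H: 1->2; 1->4; 2->5; 4->3    (typed and untyped son; each with one son
#                                  of the opposite typing status)
#   I: 1->4; 4->2; 4->5; 5->3    (untyped son with a typed son and an
#                                  untyped son, whose son is typed)
#
# The closed forms store, per scenario, P(h^v)(z) and the numerators
# p_x * P(h^v) for each applicable x. A handful of Table entries in the
# source material carry dropped coefficients; the catalogue stores the forms
# that the exact oracle on the structures reproduces to 1e-12, and the
# fixture self-check (validate_all_fixtures) enforces that agreement.

fixture_structures <- function() {
  list(
    A = list(father = c(`2` = "1"), typed = "1"),
    B = list(father = c(`2` = "1", `3` = "2"), typed = "1"),
    C = list(father = c(`2` = "1", `3` = "2"), typed = c("1", "2")),
    D = list(father = c(`3` = "1", `2` = "3"), typed = c("1", "2")),
    E = list(father = c(`3` = "1", `4` = "3", `2` = "4"), typed = c("1", "2")),
    F = list(father = c(`2` = "1", `3` = "2", `4` = "2", `5` = "2"),
             typed = c("1", "2")),
    G = list(father = c(`5` = "1", `2` = "5", `3` = "5", `4` = "5"),
             typed = c("1", "2", "3", "4")),
    H = list(father = c(`2` = "1", `4` = "1", `5` = "2", `3` = "4"),
             typed = c("1", "2", "3")),
    I = list(father = c(`4` = "1", `2` = "4", `5` = "4", `3` = "5"),
             typed = c("1", "2", "3"))
  )
}

fixture_catalogue <- function() {
  q <- function(z) 1 - 2 * z  # per-meiosis stay probability
  list(
    A01 = list(letter = "A", assign = c(),
               pv = function(z) rep(1, length(z)),
               px = list(`1` = function(z) q(z))),
    B01 = list(letter = "B", assign = c(),
               pv = function(z) rep(1, length(z)),
               px = list(`1` = function(z) 2 * z * (1 - z),
                         `2` = function(z) q(z)^2)),
    C01 = list(letter = "C", assign = c(`2` = 0),
               pv = function(z) q(z),
               px = list(`1` = function(z) q(z)^2)),
    C02 = list(letter = "C", assign = c(`2` = 1),
               pv = function(z) z,
               px = list(`1` = function(z) z^2)),
    D01 = list(letter = "D", assign = c(`2` = 0),
               pv = function(z) 2 * z^2 + q(z)^2,
               px = list(`1` = function(z) q(z)^2)),
    D02 = list(letter = "D", assign = c(`2` = 1),
               pv = function(z) 2 * z * q(z),
               px = list(`1` = function(z) z * q(z))),
    E01 = list(letter = "E", assign = c(`2` = 0),
               pv = function(z) 6 * z^2 * q(z) + q(z)^3,
               px = list(`1` = function(z) 4 * z^2 * q(z),
                         `2` = function(z) q(z)^3)),
    E02 = list(letter = "E", assign = c(`2` = 1),
               pv = function(z) 3 * z^3 + 3 * z * q(z)^2,
               px = list(`1` = function(z) 2 * z^3 + z * q(z)^2,
                         `2` = function(z) z * q(z)^2)),
    E03 = list(letter = "E", assign = c(`2` = 2),
               pv = function(z) 3 * z^2 * q(z),
               px = list(`1` = function(z) z^2 * q(z),
                         `2` = function(z) rep(0, length(z)))),
    F01 = list(letter = "F", assign = c(`2` = 0),
               pv = function(z) q(z),
               px = list(`1` = function(z) 12 * z^2 * q(z)^2,
                         `2` = function(z) 6 * z * q(z)^3,
                         `3` = function(z) q(z)^4)),
    F02 = list(letter = "F", assign = c(`2` = 1),
               pv = function(z) z,
               px = list(`1` = function(z) 3 * z^2 * (1 - z)^2,
                         `2` = function(z) 3 * z^3 * (1 - z),
                         `3` = function(z) z^4)),
    G01 = list(letter = "G", assign = c(`2` = 0, `3` = 0, `4` = 0),
               pv = function(z) 2 * z^4 + q(z)^4,
               px = list(`1` = function(z) q(z)^4)),
    G02 = list(letter = "G", assign = c(`2` = 1, `3` = 0, `4` = 0),
               pv = function(z) z^3 * q(z) + z * q(z)^3,
               px = list(`1` = function(z) z * q(z)^3)),
    G03 = list(letter = "G", assign = c(`2` = 1, `3` = 1, `4` = 0),
               pv = function(z) 2 * z^2 * q(z)^2,
               px = list(`1` = function(z) z^2 * q(z)^2)),
    G04 = list(letter = "G", assign = c(`2` = 1, `3` = 1, `4` = 1),
               pv = function(z) z^3 * q(z) + z * q(z)^3,
               px = list(`1` = function(z) z^3 * q(z))),
    H01 = list(letter = "H", assign = c(`2` = 0, `3` = 0),
               pv = function(z) 4 * z^3 * q(z) + 2 * z * (1 - z) * q(z)^2 + q(z)^4,
               px = list(`1` = function(z) 2 * z * (1 - z) * q(z)^2,
                         `2` = function(z) q(z)^4)),
    H02 = list(letter = "H", assign = c(`2` = 0, `3` = 1),
               pv = function(z) 2 * z * q(z)^2,
               px = list(`1` = function(z) z * q(z)^2,
                         `2` = function(z) z * q(z)^3)),
    H03 = list(letter = "H", assign = c(`2` = 0, `3` = 2),
               pv = function(z) z^2 * q(z),
               px = list(`1` = function(z) z^2 * q(z)^2,
                         `2` = function(z) rep(0, length(z)))),
    H04 = list(letter = "H", assign = c(`2` = 1, `3` = 0),
               pv = function(z) 2 * z^3 + z * q(z)^2,
               px = list(`1` = function(z) z * (1 - z) * q(z)^2 + 2 * z^4,
                         `2` = function(z) z^2 * q(z)^2)),
    H05 = list(letter = "H", assign = c(`2` = 1, `3` = 1),
               pv = function(z) 2 * z^2 * q(z),
               px = list(`1` = function(z) z^2 * q(z),
                         `2` = function(z) z^3 * q(z))),
    H06 = list(letter = "H", assign = c(`2` = 1, `3` = 2),
               pv = function(z) z^3,
               px = list(`1` = function(z) z^4,
                         `2` = function(z) rep(0, length(z)))),
    I01 = list(letter = "I", assign = c(`2` = 0, `3` = 0),
               pv = function(z) 4 * z^3 * q(z) + 2 * z^2 * q(z)^2 + q(z)^4,
               px = list(`1` = function(z) 2 * z^3 * q(z) + 2 * z^2 * q(z)^2,
                         `2` = function(z) q(z)^4)),
    I02 = list(letter = "I", assign = c(`2` = 0, `3` = 1),
               pv = function(z) 3 * z^4 + z^2 * q(z)^2 + 2 * z * q(z)^3,
               px = list(`1` = function(z) 2 * z^4 + z * q(z)^3,
                         `2` = function(z) z * q(z)^3)),
    I03 = list(letter = "I", assign = c(`2` = 0, `3` = 2),
               pv = function(z) 2 * z^3 * q(z) + z^2 * q(z)^2,
               px = list(`1` = function(z) z^2 * q(z)^2,
                         `2` = function(z) rep(0, length(z)))),
    I04 = list(letter = "I", assign = c(`2` = 0, `3` = 3),
               pv = function(z) z^4,
               px = list(`1` = function(z) rep(0, length(z)),
                         `2` = function(z) rep(0, length(z)))),
    I05 = list(letter = "I", assign = c(`2` = 1, `3` = 0),
               pv = function(z) 2 * z^3 * q(z) + 2 * z^2 * q(z)^2 + z * q(z)^3,
               px = list(`1` = function(z) 2 * z^3 * q(z) + z^2 * q(z)^2,
                         `2` = function(z) z * q(z)^3)),
    I06 = list(letter = "I", assign = c(`2` = 1, `3` = 1),
               pv = function(z) 2 * z^3 * q(z) + 2 * z^2 * q(z)^2 + z * q(z)^3,
               px = list(`1` = function(z) z^3 * q(z) + z^2 * q(z)^2,
                         `2` = function(z) z^2 * q(z)^2)),
    I07 = list(letter = "I", assign = c(`2` = 1, `3` = 2),
               pv = function(z) z^3 * q(z) + 2 * z^2 * q(z)^2,
               px = list(`1` = function(z) z^3 * q(z),
                         `2` = function(z) rep(0, length(z)))),
    I08 = list(letter = "I", assign = c(`2` = 1, `3` = 3),
               pv = function(z) z^3 * q(z),
               px = list(`1` = function(z) rep(0, length(z)),
                         `2` = function(z) rep(0, length(z)))),
    I09 = list(letter = "I", assign = c(`2` = 2, `3` = 0),
               pv = function(z) 2 * z^3 * q(z),
               px = list(`1` = function(z) z^3 * q(z),
                         `2` = function(z) rep(0, length(z)))),
    I10 = list(letter = "I", assign = c(`2` = 2, `3` = 1),
               pv = function(z) 2 * z^4 + z^2 * q(z)^2,
               px = list(`1` = function(z) z^4,
                         `2` = function(z) rep(0, length(z)))),
    I11 = list(letter = "I", assign = c(`2` = 2, `3` = 2),
               pv = function(z) 2 * z^3 * q(z),
               px = list(`1` = function(z) rep(0, length(z)),
                         `2` = function(z) rep(0, length(z)))),
    I12 = list(letter = "I", assign = c(`2` = 2, `3` = 3),
               pv = function(z) z^4,
               px = list(`1` = function(z) rep(0, length(z)),
                         `2` = function(z) rep(0, length(z))))
  )
}

#' List the catalogued validation scenarios
#'
#' @return character vector of scenario ids (`"A01"` .. `"I12"`).
#' @export
ystr_scenarios <- function() names(fixture_catalogue())

#' Build an elementary validation scenario
#'
#' Returns a fully specified case for one of the catalogued elementary
#' pedigrees: the pedigree structure, the typed haplotypes implied by the
#' allele assignment (suspect allele = `base_allele`, other typed members
#' offset as catalogued) and a single-marker mutation model.
#'
#' @param id scenario id, see [ystr_scenarios()].
#' @param mu single-marker mutation rate (default 0.1, the highest of the
#'   three catalogued test rates 0.1, 0.02, 0.005).
#' @param base_allele absolute repeat count assigned to the suspect; results
#'   are invariant to it (alleles are shifted so the suspect is the origin).
#' @return list with `case` (a [case_configuration()]), `model` (a
#'   [mutation_model()]) and `scenario` (the catalogue entry, incl. closed
#'   forms).
#' @examples
#' sc <- build_scenario("B01", mu = 0.1)
#' exact_distribution_dp(sc$case, sc$model)$dist
#' @export
build_scenario <- function(id, mu = 0.1, base_allele = 14L) {
  cat_ <- fixture_catalogue()
  if (!id %in% names(cat_))
    stop_validation("unknown scenario id `", id, "`; see ystr_scenarios()")
  entry <- cat_[[id]]
  struct <- fixture_structures()[[entry$letter]]
  ped <- pedigree(struct$father)
  typed <- list()
  for (m in struct$typed) {
    offset <- if (m == "1") 0L else as.integer(entry$assign[[m]])
    typed[[m]] <- c(M1 = base_allele + offset)
  }
  model <- mutation_model(c(M1 = mu))
  case <- case_configuration(ped, suspect = "1", typed = typed, panel = "M1")
  list(case = case, model = model,
       scenario = c(list(id = id), entry))
}

#' Exact scenario results from the closed forms
#'
#' Evaluates the catalogued polynomials at z = mu/2 and converts them to
#' P(h^v) and the full conditional distribution p_0..p_(n-k).
#'
#' @param id scenario id.
#' @param mu mutation rate.
#' @return list with `pv` and `dist` (exact `ystr_match_distribution`).
#' @export
scenario_exact <- function(id, mu) {
  cat_ <- fixture_catalogue()
  if (!id %in% names(cat_))
    stop_validation("unknown scenario id `", id, "`")
  entry <- cat_[[id]]
  z <- mu / 2
  pv <- entry$pv(z)
  struct <- fixture_structures()[[entry$letter]]
  U <- length(struct$father) + 1L - length(struct$typed)
  px <- vapply(as.character(seq_len(U)), function(x) {
    f <- entry$px[[x]]
    if (is.null(f)) 0 else f(z) / pv
  }, numeric(1))
  probs <- stats::setNames(c(1 - sum(px), px), 0:U)
  list(pv = pv, dist = new_match_distribution(probs, exact = TRUE))
}

#' Self-check of the fixture catalogue against the exact oracle
#'
#' For every catalogued scenario and mutation rate, compares the closed-form
#' P(h^v) and p_x (x >= 1) values with the enumeration oracle on the encoded
#' pedigree structure. A disagreement means the structure or a stored
#' polynomial was mistranscribed. p_0 is not a catalogued quantity (it is
#' obtained by subtraction from unity and suffers cancellation when close to
#' zero), so it is excluded from the strict relative comparison.
#'
#' @param mu_list mutation rates to check (default: the three catalogued
#'   test rates).
#' @param tol relative tolerance.
#' @return data.frame with one row per (scenario, mu): the maximum relative
#'   error over all quantities and an `ok` flag.
#' @export
validate_all_fixtures <- function(mu_list = c(0.1, 0.02, 0.005), tol = 1e-10) {
  rows <- list()
  for (id in ystr_scenarios()) {
    for (mu in mu_list) {
      sc <- build_scenario(id, mu = mu)
      oc <- exact_distribution_enum(sc$case, sc$model)
      cf <- scenario_exact(id, mu)
      rel <- function(a, b) abs(a - b) / max(abs(b), 1e-300)
      xs <- setdiff(names(cf$dist$probs), "0")
      errs <- c(rel(oc$pv, cf$pv),
                mapply(function(a, b) if (b == 0) as.numeric(a != 0) else rel(a, b),
                       oc$dist$probs[xs], cf$dist$probs[xs]))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = id, mu = mu, max_rel_err = max(errs), ok = max(errs) <= tol)
    }
  }
  do.call(rbind, rows)
}

#' Write a scenario's input files
#'
#' Materializes a catalogued scenario as the three input files the
#' command-line interface consumes: a TGF pedigree, a haplotype CSV and a
#' mutation-rate CSV.
#'
#' @param id scenario id.
#' @param dir output directory (created if needed).
#' @param mu mutation rate written to the rates file.
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_scenario_files <- function(id, dir, mu = 0.1) {
  sc <- build_scenario(id, mu = mu)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, paste0(id, "_pedigree.tgf")),
             haplotypes = file.path(dir, paste0(id, "_haplotypes.csv")),
             rates = file.path(dir, paste0(id, "_rates.csv")))
  write_tgf(sc$case$pedigree, paths[["pedigree"]])
  hap <- data.frame(id = names(sc$case$typed),
                    M1 = vapply(sc$case$typed, `[[`, integer(1), 1L))
  utils::write.csv(hap, paths[["haplotypes"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(marker = "M1", rate = mu), paths[["rates"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
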