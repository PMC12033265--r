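# Shared fixtures and a test-local brute-force oracle, deliberately written
# independently of the package internals (plain loops over expand.grid).

# A 16-member pedigree in the style of the worked example: the suspect sits
# two generations below the MRCA. Ids are arbitrary strings on purpose.
pedigree16 <- function() {
  pedigree(c(
    a1 = "mrca", a2 = "mrca", a3 = "mrca",
    suspect = "a1", b1 = "a1", b2 = "a2", b3 = "a2", b4 = "a3",
    s1 = "suspect", s2 = "suspect",
    c1 = "b2", c2 = "b2", c3 = "b4",
    d1 = "c1", d2 = "c2"))
}

# random rooted tree: each later member picks a father among earlier ones
random_pedigree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("m%02d", seq_len(n))
  father <- character(0)
  for (i in seq_len(n)[-1])
    father[ids[i]] <- ids[sample.int(i - 1L, 1L)]
  pedigree(father, root = ids[1L])
}

# random case on a random tree: haplotypes are realized by dropping mutations
# down the tree (so every typed configuration has positive probability), then
# a random subset of members is marked as typed
random_case <- function(n, seed, n_markers = 1L, mu = 0.1) {
  ped <- random_pedigree(n, seed)
  set.seed(seed + 500)
  z <- mu / 2
  alleles <- list()
  for (id in ped$members[order(ystrmatch:::pedigree_depths(ped)[ped$members])]) {
    fa <- ped$father[[id]]
    base <- if (is.na(fa)) rep(20L, n_markers) else alleles[[fa]]
    alleles[[id]] <- base + sample(c(-1L, 0L, 1L), n_markers, replace = TRUE,
                                   prob = c(z, 1 - 2 * z, z))
  }
  suspect <- sample(ped$members, 1L)
  others <- setdiff(ped$members, suspect)
  typed_ids <- c(suspect, sample(others, sample.int(length(others), 1L)))
  typed <- lapply(stats::setNames(typed_ids, typed_ids), function(id) alleles[[id]])
  model <- mutation_model(stats::setNames(rep(mu, n_markers),
                                          paste0("M", seq_len(n_markers))))
  case <- case_configuration(ped, suspect, typed, panel = model$markers)
  list(case = case, model = model)
}

# Test-local exact oracle: enumerate every untyped assignment over
# [-range, range] per marker and multiply single-step transition factors over
# the tree's directed edges as given (no re-rooting). Conditioning on the
# suspect haplotype is implicit: his allele is fixed and, with symmetric
# single-step factors, the sum over all other members of the edge products is
# the conditional probability of the typed observations.
brute_force_exact <- function(ped, suspect, typed, mu, range = NULL) {
  members <- ped$members
  untyped <- setdiff(members, names(typed))
  L <- length(typed[[suspect]])
  if (is.null(range)) range <- length(members)
  stepf <- function(d) ifelse(d == 0, 1 - mu, ifelse(abs(d) == 1, mu / 2, 0))
  grid <- if (length(untyped) == 0) data.frame(row.names = "1")
          else do.call(expand.grid,
                       rep(list(seq.int(-range, range)), length(untyped) * L))
  pv <- 0
  mass <- rep(0, length(untyped) + 1L)
  val <- function(row, id, j) {
    if (id %in% names(typed)) typed[[id]][[j]]
    else grid[row, (match(id, untyped) - 1L) * L + j]
  }
  for (r in seq_len(nrow(grid))) {
    w <- 1
    for (son in members[!is.na(ped$father[members])]) {
      fa <- ped$father[[son]]
      for (j in seq_len(L)) w <- w * stepf(val(r, son, j) - val(r, fa, j))
      if (w == 0) break
    }
    if (w == 0) next
    pv <- pv + w
    m <- sum(vapply(untyped, function(u)
      all(vapply(seq_len(L), function(j) val(r, u, j) == 0, logical(1))),
      logical(1)))
    mass[m + 1L] <- mass[m + 1L] + w
  }
  list(pv = pv, probs = stats::setNames(mass / pv, seq_along(mass) - 1L))
}

# build a catalogued scenario with every typed allele offset negated
build_scenario_flipped <- function(id, mu) {
  sc <- build_scenario(id, mu = mu)
  suspect_hap <- sc$case$typed[[sc$case$suspect]]
  typed <- lapply(sc$case$typed, function(h) 2L * suspect_hap - h)
  case <- case_configuration(sc$case$pedigree, sc$case$suspect, typed,
                             panel = sc$case$panel)
  list(case = case, model = sc$model)
}

expect_printed <- function(value, printed, half_ulp) {
  expect_lte(abs(value - printed), half_ulp)
}
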