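test_that("TGF reading recovers structure, root and labels", {
  tgf <- c("r MRCA", "a", "b son of a", "#", "r a", "a b")
  f <- withr::local_tempfile(lines = tgf, fileext = ".tgf")
  ped <- read_tgf(f)
  expect_s3_class(ped, "ystr_pedigree")
  expect_setequal(ped$members, c("r", "a", "b"))
  expect_equal(ped$root, "r")
  expect_equal(unname(ped$father[["b"]]), "a")
  expect_equal(unname(ped$labels[["b"]]), "son of a")

  one <- withr::local_tempfile(lines = c("solo", "#"), fileext = ".tgf")
  ped1 <- read_tgf(one)
  expect_equal(length(ped1$members), 1L)
  expect_equal(ped1$root, "solo")
})

test_that("a 16-member pedigree file parses with the MRCA as root", {
  f <- withr::local_tempfile(fileext = ".tgf")
  write_tgf(pedigree16(), f)
  ped <- read_tgf(f)
  expect_equal(length(ped$members), 16L)
  expect_equal(ped$root, "mrca")
  expect_equal(nrow(ystrmatch:::pedigree_edges(ped)), 15L)
})

test_that("TGF write/read round-trip is the identity on structure", {
  for (seed in 1:4) {
    ped <- random_pedigree(sample(2:12, 1L), seed)
    f <- withr::local_tempfile(fileext = ".tgf")
    write_tgf(ped, f)
    back <- read_tgf(f)
    expect_setequal(back$members, ped$members)
    expect_equal(back$father[sort(names(back$father))],
                 ped$father[sort(names(ped$father))])
    expect_equal(back$root, ped$root)
    expect_equal(sum(!is.na(back$father)), length(ped$members) - 1L)
  }
})

test_that("malformed TGF files raise distinct parse errors naming the problem", {
  read_lines <- function(lines) {
    f <- withr::local_tempfile(lines = lines, fileext = ".tgf")
    read_tgf(f)
  }
  expect_error(read_lines(c("a", "b", "a b")), "missing `#`",
               class = "ystr_parse_error")
  expect_error(read_lines(c("a", "a", "#")), "duplicate node id",
               class = "ystr_parse_error")
  expect_error(read_lines(c("a", "b", "c", "#", "a c", "b c")),
               "two fathers", class = "ystr_parse_error")
  expect_error(read_lines(c("a", "b", "#", "a b", "b a")),
               "no root", class = "ystr_parse_error")
  expect_error(read_lines(c("a", "b", "c", "#", "b c")),
               "disconnected", class = "ystr_parse_error")
  expect_error(read_lines(c("a", "#", "a x")), "unknown node",
               class = "ystr_parse_error")
  # cycle hanging below a valid root
  expect_error(read_lines(c("a", "b", "c", "d", "#", "a b", "c d", "d c")),
               "cycle|two fathers", class = "ystr_parse_error")
})

test_that("haplotype CSV parsing validates alleles, markers and ids", {
  f <- withr::local_tempfile(lines = c("id,M1,M2", "S,14,30", "T,15,30"))
  haps <- read_haplotypes_csv(f, panel = c("M1", "M2"))
  expect_equal(haps$S, c(M1 = 14L, M2 = 30L))
  expect_equal(haps$T, c(M1 = 15L, M2 = 30L))

  frac <- withr::local_tempfile(lines = c("id,M1", "S,13.2"))
  expect_error(read_haplotypes_csv(frac, "M1"), "not an integer",
               class = "ystr_parse_error")
  dup <- withr::local_tempfile(lines = c("id,M1", "S,1", "S,2"))
  expect_error(read_haplotypes_csv(dup, "M1"), "duplicate",
               class = "ystr_parse_error")
  wrong <- withr::local_tempfile(lines = c("id,M9", "S,1"))
  expect_error(read_haplotypes_csv(wrong, "M1"), "panel",
               class = "ystr_parse_error")
})

test_that("mutation-rate files load from CSV and JSON", {
  csv <- withr::local_tempfile(lines = c("marker,rate", "M1,0.1", "M2,0.02"))
  m1 <- read_mutation_rates(csv)
  expect_equal(m1$rates, c(M1 = 0.1, M2 = 0.02))
  js <- withr::local_tempfile(lines = '{"M1": 0.1, "M2": 0.02}')
  m2 <- read_mutation_rates(js)
  expect_equal(m2$rates, m1$rates)
})

test_that("case validation enforces invariants and flags impossible edges", {
  ped <- pedigree(c(son = "S", grandson = "son"))
  model <- mutation_model(c(M1 = 0.1))

  expect_error(
    case_configuration(ped, "S", list(son = c(M1 = 14L))),
    "suspect", class = "ystr_validation_error")
  expect_error(
    case_configuration(ped, "S", list(S = c(M1 = 14L), ghost = c(M1 = 14L))),
    "not in the pedigree", class = "ystr_validation_error")

  clean <- case_configuration(ped, "S",
                              list(S = c(M1 = 14L), son = c(M1 = 15L)))
  expect_length(validate_case(clean, model), 0L)

  jump <- case_configuration(ped, "S",
                             list(S = c(M1 = 14L), son = c(M1 = 16L)))
  w <- validate_case(jump, model)
  expect_length(w, 1L)
  expect_match(w, "2 repeats")
})
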