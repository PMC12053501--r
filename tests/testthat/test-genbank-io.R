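test_that("a minimal record with one plus-strand gene parses exactly", {
  set.seed(101)
  genome <- random_dna(500)
  path <- write_genbank_fixture(genome, list(
    list(kind = "gene", location = "1..306", quals = c(gene = "ndhE"))))
  rec <- parse_plastome(path)
  expect_s3_class(rec, "plastome_record")
  expect_identical(rec$length_bp, 500L)
  expect_true(rec$is_circular)
  obs <- extract_gene(rec, "ndhE")
  expect_length(obs, 1L)
  expect_identical(obs[[1]]$length_bp, 306L)
  expect_identical(obs[[1]]$segments, list(c(0L, 306L)))
  expect_identical(obs[[1]]$strand, "+")
  expect_identical(obs[[1]]$sequence, substr(genome, 1, 306))
})

test_that("inverted-repeat duplicates are kept with distinct copy_index", {
  set.seed(102)
  genome <- random_dna(6000)
  path <- write_genbank_fixture(genome, list(
    list(kind = "gene", location = "101..2342", quals = c(gene = "ndhB")),
    list(kind = "gene", location = "3001..4800", quals = c(gene = "ndhB"))))
  obs <- extract_gene(parse_plastome(path), "ndhB")
  expect_length(obs, 2L)
  expect_identical(vapply(obs, `[[`, 1L, "copy_index"), 1:2)
  expect_identical(vapply(obs, `[[`, 1L, "length_bp"), c(2242L, 1800L))
})

test_that("origin-spanning join on a circular record matches the rotation oracle", {
  set.seed(103)
  genome <- random_dna(1000)
  path <- write_genbank_fixture(genome, list(
    list(kind = "gene", location = "join(951..1000,1..50)",
         quals = c(gene = "ndhC"))))
  obs <- extract_gene(parse_plastome(path), "ndhC")[[1]]
  expect_identical(obs$length_bp, 100L)
  expect_identical(obs$segments, list(c(950L, 1000L), c(0L, 50L)))
  # oracle: rotate the sequence so the feature becomes contiguous
  rotated <- paste0(substr(genome, 951, 1000), substr(genome, 1, 950))
  expect_identical(obs$sequence, substr(rotated, 1, 100))
})

test_that("an origin-crossing single span (end > length) is split on circular records", {
  set.seed(110)
  genome <- random_dna(1000)
  path <- write_genbank_fixture(genome, list(
    list(kind = "gene", location = "951..1050", quals = c(gene = "ndhC"))))
  obs <- extract_gene(parse_plastome(path), "ndhC")[[1]]
  expect_identical(obs$segments, list(c(950L, 1000L), c(0L, 50L)))
  expect_identical(obs$sequence,
                   paste0(substr(genome, 951, 1000), substr(genome, 1, 50)))
})

test_that("minus-strand extraction equals the reverse complement of plus-strand", {
  set.seed(104)
  genome <- random_dna(800)
  path <- write_genbank_fixture(genome, list(
    list(kind = "gene", location = "101..400", quals = c(gene = "ndhG")),
    list(kind = "gene", location = "complement(101..400)",
         quals = c(gene = "ndhH"))))
  rec <- parse_plastome(path)
  fwd <- extract_gene(rec, "ndhG")[[1]]
  rev <- extract_gene(rec, "ndhH")[[1]]
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd$sequence)))
  expect_identical(rev$sequence, oracle)
  expect_identical(rev$strand, "-")
})

test_that("CDS is preferred over gene for the same gene name", {
  set.seed(105)
  genome <- random_dna(600)
  path <- write_genbank_fixture(genome, list(
    list(kind = "gene", location = "1..312", quals = c(gene = "ndhE")),
    list(kind = "CDS", location = "4..309", quals = c(gene = "ndhE"))))
  obs <- extract_gene(parse_plastome(path), "ndhE")
  expect_length(obs, 1L)
  expect_identical(obs[[1]]$length_bp, 306L)
  expect_identical(obs[[1]]$sequence, substr(genome, 4, 309))
})

test_that("gene names normalize case-insensitively and via the synonym table", {
  expect_identical(normalize_gene_name(c("NDHB", " ndhe ", "RBCL")),
                   c("ndhB", "ndhE", "rbcL"))
  expect_identical(normalize_gene_name("NADH dehydrogenase subunit 2"),
                   "ndhB")
  expect_identical(normalize_gene_name("totallyNovelGene"),
                   "totallyNovelGene")
  set.seed(106)
  path <- write_genbank_fixture(random_dna(500), list(
    list(kind = "CDS", location = "10..315",
         quals = c(product = "NADH dehydrogenase subunit 4L"))))
  expect_length(extract_gene(parse_plastome(path), "ndhE"), 1L)
})

test_that("absence, unresolvable locations and missing ORIGIN behave per contract", {
  set.seed(107)
  genome <- random_dna(400)
  path <- write_genbank_fixture(genome, list(
    list(kind = "gene", location = "1..99", quals = c(gene = "ndhA")),
    list(kind = "gene", location = "join(10..50,complement(60..90))",
         quals = c(gene = "ndhB"))))
  expect_warning(rec <- parse_plastome(path), "unresolvable location")
  expect_identical(extract_gene(rec, "ndhF"), list())
  expect_length(extract_gene(rec, "ndhB"), 0L)
  expect_length(extract_gene(rec, "ndhA"), 1L)

  bad <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp DNA linear", "FEATURES", "//"), bad)
  expect_error(parse_plastome(bad), "ORIGIN")
})

test_that("gzip-compressed records parse identically to plain ones", {
  set.seed(108)
  genome <- random_dna(700)
  feats <- list(list(kind = "gene", location = "5..310",
                     quals = c(gene = "ndhJ")))
  plain <- write_genbank_fixture(genome, feats)
  gz <- tempfile(fileext = ".gb.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(plain), con)
  close(con)
  a <- parse_plastome(plain)
  b <- parse_plastome(gz)
  expect_identical(a$sequence, b$sequence)
  expect_identical(extract_gene(a, "ndhJ")[[1]]$sequence,
                   extract_gene(b, "ndhJ")[[1]]$sequence)
})

test_that("parsing generator output round-trips every planted gene exactly", {
  tree <- simulate_tree(5, seed = 21)
  cfg <- simulation_config(5, tree_seed = 21, mutation_seed = 22,
                           ir_genes = "ndhB", span_origin = TRUE)
  cohort <- simulate_cohort(tree, cfg, dir = tempfile())
  for (tip in tree$tip.label) {
    rec <- parse_plastome(cohort$files[[tip]])
    for (g in names(cfg$genes)) {
      obs <- extract_gene(rec, g)
      planted <- cohort$sequences[[tip]][[g]]
      expect_length(obs, if (g == "ndhB") 2L else 1L)
      for (o in obs) {
        expect_identical(o$sequence, planted)
        expect_identical(o$strand, cohort$strands[[g]])
        expect_identical(o$length_bp, nchar(planted))
      }
    }
  }
})

test_that("write_gene_fasta round-trips sequences and rejects empty input", {
  set.seed(109)
  obs <- list(make_obs("ndhJ", sequence = random_dna(477), sample_id = "a"),
              make_obs("ndhJ", sequence = random_dna(301), sample_id = "a",
                       copy_index = 2L))
  path <- tempfile(fileext = ".fasta")
  write_gene_fasta(obs, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_identical(names(back), c("a|ndhJ|1", "a|ndhJ|2"))
  expect_identical(as.character(back[[1]]), obs[[1]]$sequence)
  expect_identical(as.character(back[[2]]), obs[[2]]$sequence)
  # 70-column wrap
  expect_lte(max(nchar(readLines(path))), 70L)
  expect_error(write_gene_fasta(list(), tempfile()), "no observations")
})
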