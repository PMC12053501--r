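# codon-safe building blocks: AAA codons carry no stops
orf_no_stop <- function(n_bp) strrep("A", n_bp)

test_that("detect_premature_stop finds the first internal stop only", {
  expect_null(detect_premature_stop("ATGAAATAA"))      # terminal TAA
  expect_identical(detect_premature_stop("ATGTAAAAATAA"), 2L)
  expect_null(detect_premature_stop("ATGAAAT"))        # remainder ignored
  expect_identical(detect_premature_stop("ATGTGAAAATAGAAA"), 2L)
  # a stop inside the trailing partial codon is not a codon at all
  expect_null(detect_premature_stop("ATGAAATA"))
  expect_error(detect_premature_stop("AT"), "at least 3")
  # all three table-11 stops are recognized
  for (s in c("TAA", "TAG", "TGA")) {
    expect_identical(detect_premature_stop(paste0("ATG", s, "AAA")), 2L)
  }
  # ambiguity letters never match a stop
  expect_null(detect_premature_stop("ATGTNAAAATAA"))
})

test_that("classify_gene applies the four-state rule with precedence", {
  th <- audit_thresholds()
  # absent -> lost
  st <- classify_gene(list(), 2242, th)
  expect_identical(st$state, "lost")
  expect_identical(st$observed_length_bp, 0L)
  # 400/2242 = 0.178 < 0.20 -> lost
  st <- classify_gene(list(make_obs("ndhB", sequence = orf_no_stop(400))),
                      2242, th)
  expect_identical(st$state, "lost")
  expect_equal(st$length_ratio, 400 / 2242)
  # full length, no internal stop -> functional
  full <- paste0("ATG", strrep("AAA", 2242 %/% 3 - 2), "TAA",
                 strrep("A", 2242 %% 3))
  st <- classify_gene(list(make_obs("ndhB", sequence = full)), 2242, th)
  expect_identical(st$state, "functional")
  expect_equal(st$length_ratio, 1)
  # full length with a stop at codon 100 -> truncated
  trunc <- full
  substr(trunc, 298, 300) <- "TGA"
  st <- classify_gene(list(make_obs("ndhB", sequence = trunc)), 2242, th)
  expect_identical(st$state, "truncated")
  expect_identical(st$premature_stop_codon_index, 100L)
  # 1500/2242 = 0.669: inside (0.20, 0.80) -> pseudogenized
  st <- classify_gene(list(make_obs("ndhB", sequence = orf_no_stop(1500))),
                      2242, th)
  expect_identical(st$state, "pseudogenized")
  expect_error(classify_gene(list(), 0), "positive")
})

test_that("boundary ratios follow the strict below/above reading", {
  th <- audit_thresholds()
  ref <- 1000
  # exactly 20% is NOT lost (and is below 80%, hence pseudogenized)
  st <- classify_gene(list(make_obs("g", sequence = orf_no_stop(200))),
                      ref, th)
  expect_identical(st$state, "pseudogenized")
  # exactly 80% and exactly 120% are NOT pseudogenized
  st <- classify_gene(list(make_obs("g", sequence = orf_no_stop(800))),
                      ref, th)
  expect_identical(st$state, "functional")
  st <- classify_gene(list(make_obs("g", sequence = orf_no_stop(1200))),
                      ref, th)
  expect_identical(st$state, "functional")
  # just outside the closed window
  st <- classify_gene(list(make_obs("g", sequence = orf_no_stop(1201))),
                      ref, th)
  expect_identical(st$state, "pseudogenized")
  st <- classify_gene(list(make_obs("g", sequence = orf_no_stop(199))),
                      ref, th)
  expect_identical(st$state, "lost")
})

test_that("an internal stop dominates a length violation by default, not under pseudogenized_only", {
  th <- audit_thresholds()
  ref <- 999
  with_stop <- paste0("ATG", "TAA", strrep("AAA", 164))  # 501 bp, stop at 2
  st <- classify_gene(list(make_obs("g", sequence = with_stop)), ref, th)
  expect_identical(st$state, "truncated")
  st <- classify_gene(list(make_obs("g", sequence = with_stop)), ref, th,
                      truncation_scope = "pseudogenized_only")
  expect_identical(st$state, "truncated")  # outside window, stop refines it
  # full-length copy with internal stop: truncated under "any", functional
  # under the annotation-driven alternative
  full_stop <- paste0("ATG", "TAA", strrep("AAA", 330), "TAA")  # 999 bp
  st <- classify_gene(list(make_obs("g", sequence = full_stop)), ref, th)
  expect_identical(st$state, "truncated")
  st <- classify_gene(list(make_obs("g", sequence = full_stop)), ref, th,
                      truncation_scope = "pseudogenized_only")
  expect_identical(st$state, "functional")
  # check_stops = FALSE reproduces the annotation-only assessment
  st <- classify_gene(list(make_obs("g", sequence = full_stop)), ref, th,
                      check_stops = FALSE)
  expect_identical(st$state, "functional")
})

test_that("multiple copies classify by the longest copy", {
  th <- audit_thresholds()
  obs <- list(make_obs("ndhB", sequence = orf_no_stop(300), copy_index = 2L),
              make_obs("ndhB", sequence = orf_no_stop(2242)))
  st <- classify_gene(obs, 2242, th)
  expect_identical(st$state, "functional")
  expect_identical(st$observed_length_bp, 2242L)
})

test_that("build_status_matrix is exhaustive, exclusive and TSV-serializable", {
  tree <- simulate_tree(10, seed = 51)
  cfg <- simulation_config(10, tree_seed = 51, mutation_seed = 52)
  cohort <- simulate_cohort(tree, cfg, dir = tempfile())
  recs <- lapply(cohort$files, parse_plastome)
  refs <- determine_reference_lengths(recs)
  sm <- build_status_matrix(recs, refs = refs)
  expect_identical(dim(sm$status), c(10L, 11L))
  expect_true(all(sm$status %in%
                    c("functional", "truncated", "pseudogenized", "lost")))
  expect_true(all(sm$status == "functional"))  # all-intact scenario
  counts <- summary(sm)
  expect_identical(sum(counts$functional), 110L)
  wide <- tempfile(); long <- tempfile()
  write_status_matrix(sm, wide, "wide")
  write_status_matrix(sm, long, "long")
  w <- utils::read.delim(wide, check.names = FALSE,
                         colClasses = "character")
  expect_identical(dim(w), c(10L, 12L))
  expect_true(all(w[, -1] == "F"))
  l <- utils::read.delim(long)
  expect_identical(nrow(l), 110L)
  expect_error(build_status_matrix(recs, genes = c("ndhA", "nope"),
                                   refs = refs), "nope")
})

test_that("planted states are recovered exactly across a mixed scenario", {
  tree <- simulate_tree(12, seed = 53)
  clades <- pick_disjoint_clades(tree, 3, min_size = 2)
  sc <- data.frame(
    gene = c("ndhF", "ndhF", "ndhB", "ndhJ", "ndhD"),
    tips = c(paste(clades[[1]], collapse = ";"),
             paste(clades[[2]], collapse = ";"),
             paste(clades[[3]], collapse = ";"),
             clades[[1]][1], clades[[2]][1]),
    state = c("lost", "lost", "truncated", "pseudogenized", "lost"))
  cfg <- simulation_config(12, tree_seed = 53, mutation_seed = 54,
                           state_scenario = sc, lost_mode = "fragment")
  cohort <- simulate_cohort(tree, cfg, dir = tempfile())
  recs <- lapply(cohort$files, parse_plastome)
  refs <- determine_reference_lengths(recs)
  sm <- build_status_matrix(recs, refs = refs)
  merged <- merge(cohort$truth, sm$cells, by = c("sample_id", "gene_name"))
  expect_identical(nrow(merged), 12L * 11L)
  expect_identical(sum(merged$planted_state != merged$state), 0L)
  # planted stop positions surface in the long output
  tr <- merged[merged$planted_state == "truncated", ]
  expect_true(all(tr$premature_stop_codon_index ==
                    tr$planted_stop_codon_index))
})

test_that("property: raising lost_fraction only ever converts states to lost", {
  tree <- simulate_tree(8, seed = 55)
  clades <- pick_disjoint_clades(tree, 2, min_size = 2)
  sc <- data.frame(gene = c("ndhK", "ndhC"),
                   tips = vapply(clades, paste, "", collapse = ";"),
                   state = c("pseudogenized", "truncated"))
  cfg <- simulation_config(8, tree_seed = 55, mutation_seed = 56,
                           state_scenario = sc, lost_mode = "fragment")
  cohort <- simulate_cohort(tree, cfg, dir = tempfile())
  recs <- lapply(cohort$files, parse_plastome)
  refs <- determine_reference_lengths(recs)
  lo <- build_status_matrix(recs, refs = refs,
                            thresholds = audit_thresholds())
  hi <- build_status_matrix(recs, refs = refs,
                            thresholds = audit_thresholds(lost_fraction =
                                                            0.6))
  changed <- lo$status != hi$status
  expect_true(all(hi$status[changed] == "lost"))
  expect_true(all(lo$status[changed] != "lost"))
  # and at least one cell did move (the 50%-length pseudogenes)
  expect_gt(sum(changed), 0)
})
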