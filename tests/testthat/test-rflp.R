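test_that("an enzyme cutting one allele at the variation is specific", {
  j <- judge_rflp(parse_input("ACGG[A/C]TTTTTT"), paper_catalog())
  v <- j$verdicts
  expect_equal(nrow(v), 1)
  expect_identical(v$enzyme, "TspGWI")
  expect_true(v$specific)
  expect_identical(v$cut_alleles, "A")
  expect_identical(v$uncut_alleles, "C")
  expect_equal(v$n_background_hits, 0)
  expect_identical(v$strand, "+")
  expect_true(all(c("BspGI", "EcoRI") %in% j$no_hit_enzymes))
})

test_that("a repeated background site excludes the enzyme", {
  j <- judge_rflp(parse_input("ACGG[A/C]TTTTTTACGGATTT"), paper_catalog())
  v <- j$verdicts[j$verdicts$enzyme == "TspGWI", ]
  expect_false(v$specific)
  expect_identical(v$cut_alleles, "A")              # still cuts at the variation
  expect_gte(v$n_background_hits, 2)                # downstream ACGGA in both alleles
})

test_that("IUPAC enzymes can be excluded and re-enabled", {
  t <- parse_input("AATTTCTGG[A/G]CCCTAACGGT")
  cat1 <- iupac_site_catalog()

  jg <- judge_rflp(t, cat1, judge_options(include_iupac = FALSE))
  spec_general <- jg$verdicts$enzyme[jg$verdicts$specific]
  expect_identical(spec_general, "BspGI")
  expect_identical(jg$verdicts$cut_alleles[jg$verdicts$specific], "A")

  ja <- judge_rflp(t, cat1, judge_options(include_iupac = TRUE))
  spec_all <- ja$verdicts$enzyme[ja$verdicts$specific]
  expect_true(all(spec_general %in% spec_all))
  expect_gt(length(spec_all), length(spec_general))  # strict superset
  expect_true(all(c("DegI", "DegII", "DegIII") %in% spec_all))
})

test_that("verdict allele sets partition the alleles", {
  set.seed(131)
  fx <- rebase_fixture(20, seed = 17, iupac_fraction = 0.3)
  for (i in 1:10) {
    t <- rand_template(n = 40, k = 1, allow_indel = TRUE)
    j <- judge_rflp(t, fx$catalog)
    v <- j$verdicts
    for (r in seq_len(nrow(v))) {
      cut <- strsplit(v$cut_alleles[r], ",", fixed = TRUE)[[1]]
      uncut <- strsplit(v$uncut_alleles[r], ",", fixed = TRUE)[[1]]
      expect_setequal(c(cut, uncut), j$alleles)
      expect_length(intersect(cut, uncut), 0)
      if (v$specific[r]) {
        expect_gt(length(cut), 0)
        expect_lt(length(cut), length(j$alleles))
        expect_equal(v$n_background_hits[r], 0)
      }
    }
  }
})

test_that("degenerate inputs and empty catalogs are rejected", {
  expect_error(judge_rflp(parse_input("ACGT"), paper_catalog()), "no variation")
  empty <- parse_rebase("")
  expect_error(judge_rflp(parse_input("ACGG[A/C]TT"), empty), "empty enzyme catalog")
  expect_error(judge_options(min_len = 8, max_len = 4), "min_len")
})

test_that("deletion alleles are judged at the insertion point", {
  cat1 <- enzyme_catalog(name = c("JuncI", "UpI"),
                         recognition = c("GGTT", "ACGG"),
                         suppliers = c("N", "N"))
  j <- judge_rflp(parse_input("ACGG[-/A]TTT"), cat1)
  v <- j$verdicts
  junc <- v[v$enzyme == "JuncI", ]
  # GGTT straddles the deletion junction in the "-" allele only
  expect_true(junc$specific)
  expect_identical(junc$cut_alleles, "-")
  # ACGG sits upstream of the site in both alleles: background, not specific
  up <- v[v$enzyme == "UpI", ]
  expect_false(up$specific)
  expect_identical(up$cut_alleles, "")
  expect_equal(up$n_background_hits, 2)
})

test_that("permuting allele order changes labels only", {
  cat1 <- paper_catalog()
  j1 <- judge_rflp(parse_input("ACGG[A/C]TTTTTT"), cat1)
  j2 <- judge_rflp(parse_input("ACGG[C/A]TTTTTT"), cat1)
  expect_identical(j1$verdicts$enzyme[j1$verdicts$specific],
                   j2$verdicts$enzyme[j2$verdicts$specific])
  expect_identical(j2$verdicts$cut_alleles, "A")
})

test_that("identical alleles never yield a specific enzyme", {
  t <- rflpfinder:::.new_template(segments = c("ACGG", "TTTTTT"),
                                  sites = list(c("A", "A")),
                                  dialect = "bracket")
  j <- judge_rflp(t, paper_catalog())
  expect_false(any(j$verdicts$specific))
})

test_that("adding enzymes to the catalog never removes specificity", {
  set.seed(141)
  base <- rebase_fixture(8, seed = 23)$catalog
  extra <- rebase_fixture(20, seed = 29)$catalog
  for (i in 1:8) {
    t <- rand_template(n = 35, k = 1)
    j_small <- judge_rflp(t, base)
    grown <- rbind(as.data.frame(base), as.data.frame(extra[-(1:2), ]))
    class(grown) <- c("rebase_catalog", "data.frame")
    j_big <- judge_rflp(t, grown)
    spec_small <- j_small$verdicts$enzyme[j_small$verdicts$specific]
    spec_big <- j_big$verdicts$enzyme[j_big$verdicts$specific]
    expect_true(all(spec_small %in% spec_big))
  }
})

test_that("disabling IUPAC enzymes restricts to the general subset", {
  set.seed(151)
  fx <- rebase_fixture(25, seed = 31, iupac_fraction = 0.5)
  for (i in 1:8) {
    t <- rand_template(n = 35, k = 1)
    with_i <- judge_rflp(t, fx$catalog, judge_options(include_iupac = TRUE))
    without <- judge_rflp(t, fx$catalog, judge_options(include_iupac = FALSE))
    expect_true(all(without$verdicts$enzyme %in% with_i$verdicts$enzyme))
    expect_true(all(without$verdicts$enzyme_class == "general"))
    gen_with <- with_i$verdicts[with_i$verdicts$enzyme_class == "general",
                                c("enzyme", "specific")]
    gen_without <- without$verdicts[, c("enzyme", "specific")]
    expect_equal(gen_without[order(gen_without$enzyme), ],
                 gen_with[order(gen_with$enzyme), ], ignore_attr = TRUE)
  }
})

test_that("the specific set is invariant under strand reversal", {
  set.seed(161)
  fx <- rebase_fixture(15, seed = 37, iupac_fraction = 0.3)
  for (i in 1:20) {
    t <- rand_template(n = 40, k = 1)
    j_fwd <- judge_rflp(t, fx$catalog)
    j_rev <- judge_rflp(reverse_complement_template(t), fx$catalog)
    expect_setequal(j_fwd$verdicts$enzyme[j_fwd$verdicts$specific],
                    j_rev$verdicts$enzyme[j_rev$verdicts$specific])
  }
})

test_that("multi-site templates judge one site with others frozen", {
  cat1 <- paper_catalog()
  # site 2 is the informative one; site 1 frozen at its first allele (G)
  t <- parse_input("AC[G/T]G[A/C]TTTTTT")
  j <- judge_rflp(t, cat1, judge_options(site_index = 2))
  expect_identical(j$verdicts$enzyme[j$verdicts$specific], "TspGWI")
  expect_identical(vapply(j$allele_sequences, `[[`, "", "sequence"),
                   c("ACGGATTTTTT", "ACGGCTTTTTT"))
  expect_error(judge_rflp(t, cat1, judge_options(site_index = 3)), "out of range")
})

test_that("a flanking window narrows the judged region", {
  cat1 <- paper_catalog()
  t <- parse_input("ACGG[A/C]TTTTTTACGGATTT")
  full <- judge_rflp(t, cat1)
  expect_false(any(full$verdicts$specific))
  # radius 4 leaves the downstream repeat outside the window
  windowed <- judge_rflp(t, cat1, judge_options(flank_radius = 4))
  expect_identical(windowed$verdicts$enzyme[windowed$verdicts$specific], "TspGWI")
})

test_that("classification buckets are exhaustive and exclusive", {
  j <- judge_rflp(parse_input("AATTTCTGG[A/G]CCCTAACGGT"), iupac_site_catalog())
  cl <- classify_results(j)
  v <- j$verdicts
  expect_setequal(c(cl$iupac, cl$general), v$enzyme)
  expect_setequal(c(cl$commercial, cl$non_commercial), v$enzyme)
  expect_length(intersect(cl$iupac, cl$general), 0)
  expect_true("BspGI" %in% cl$general)
  expect_true("BspGI" %in% cl$commercial)
  expect_true(all(c("DegI", "DegII") %in% cl$iupac))
  expect_true("DegI" %in% cl$non_commercial)

  j0 <- judge_rflp(parse_input("ACGG[A/C]TT"),
                   enzyme_catalog("FarI", "GGGGGGGG"))
  cl0 <- classify_results(j0)
  expect_true(all(lengths(cl0) == 0))
})

test_that("reports join verdicts with full catalog records and round-trip", {
  cat1 <- paper_catalog()
  j <- judge_rflp(parse_input("ACGG[A/C]TTTTTT"), cat1)
  rep <- rflp_report(j, cat1)
  expect_true(all(c("enzyme", "microorganism", "source", "recognition",
                    "methylation", "suppliers", "references",
                    "availability") %in% names(rep)))
  expect_identical(rep$microorganism, "Thermus sp. GW")
  expect_match(rep$variation_hits, "A:1-5\\(\\+\\)")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tsv, "tsv")
  write_report(rep, js, "json")
  from_tsv <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  from_json <- jsonlite::fromJSON(js)
  for (cl in c("enzyme", "cut_alleles", "recognition", "suppliers"))
    expect_equal(from_tsv[[cl]], from_json[[cl]])

  # unknown enzyme: join error
  expect_error(rflp_report(j, enzyme_catalog("OtherI", "AAAA")), "not found")

  # empty verdicts: empty report
  j0 <- judge_rflp(parse_input("ACGG[A/C]TT"), enzyme_catalog("FarI", "GGGGGGGG"))
  expect_equal(nrow(rflp_report(j0, enzyme_catalog("FarI", "GGGGGGGG"))), 0)
})

test_that("batch judgment equals sequential judgment for any worker count", {
  cat1 <- iupac_site_catalog()
  templates <- lapply(c("ACGG[A/C]TTTTTT",
                        "ACGG[A/C]TTTTTTACGGATTT",
                        "AATTTCTGG[A/G]CCCTAACGGT"), parse_input)
  r1 <- judge_rflp_batch(templates, cat1, workers = 1)
  r4 <- judge_rflp_batch(templates, cat1, workers = 4)
  expect_identical(lapply(r1, `[[`, "verdicts"), lapply(r4, `[[`, "verdicts"))
  expect_identical(r1[[1]]$verdicts,
                   judge_rflp(templates[[1]], cat1)$verdicts)

  single <- judge_rflp_batch(templates[1], cat1)
  expect_length(single, 1)
  expect_identical(single[[1]]$verdicts, judge_rflp(templates[[1]], cat1)$verdicts)
})

test_that("per-template failures become error records, not aborts", {
  cat1 <- paper_catalog()
  templates <- list(parse_input("ACGG[A/C]TTTTTT"), parse_input("ACGTACGT"))
  res <- judge_rflp_batch(templates, cat1)
  expect_s3_class(res[[1]], "rflp_judgment")
  expect_s3_class(res[[2]], "rflp_error")
  expect_match(res[[2]]$message, "no variation")
  br <- batch_report(res, cat1)
  expect_true(any(nzchar(br$error)))
})
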