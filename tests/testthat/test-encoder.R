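test_that("schema has the canonical 727-column layout", {
  sch <- build_schema(10)
  expect_identical(nrow(sch), 727L)
  per_site <- table(sch$site)
  expect_identical(unname(per_site[["11"]]), 27L)
  expect_true(all(per_site[names(per_site) != "11"] == 35L))
  fam <- table(sch$family)
  expect_identical(unname(fam[["PSSM"]]), 420L)
  expect_identical(unname(fam[["AAFactor"]]), 100L)
  expect_identical(unname(fam[["Disorder"]]), 21L)
  expect_identical(unname(fam[["SecondaryStructure"]]), 63L)
  expect_identical(unname(fam[["Accessibility"]]), 42L)
  expect_identical(unname(fam[["InterfaceSurface"]]), 40L)
  expect_identical(unname(fam[["GainLoss"]]), 20L)
  expect_identical(unname(fam[["CarbonDeviation"]]), 21L)
  # centre site omits the residue-identity families
  center <- sch[sch$site == 11, ]
  expect_false(any(center$family %in%
                     c("AAFactor", "InterfaceSurface", "GainLoss")))
})

test_that("schema naming follows the AA<site>-<feature> convention", {
  sch <- build_schema(10)
  expect_true("AA10-Pssm_A" %in% sch$name)
  expect_true("AA2-Codon Diversity" %in% sch$name)
  expect_true("AA1-Secondary Structure Helix" %in% sch$name)
  expect_true("AA8-Side Chain Count of Atom_C Deviation from Mean" %in%
                sch$name)
  expect_false(anyDuplicated(sch$name) > 0)
  # pure function of flank: repeated builds are identical
  expect_identical(build_schema(10), sch)
  expect_identical(nrow(build_schema(2)), 4L * 35L + 27L)
})

test_that("carbon deviation follows the window-mean rule", {
  tab <- load_property_tables()
  # homopolymer: every residue deviates 0 from its own mean
  expect_equal(carbon_deviation(strrep("L", 21), tab), rep(0, 21))
  # all pads: every position carries the global mean count
  expect_equal(carbon_deviation(strrep("-", 21), tab), rep(0, 21))
  # mixed window: direct arithmetic over the carbon-count table
  win <- paste(c(AA_ALPHABET, "A"), collapse = "")
  counts <- c(tab$side_chain_carbons[AA_ALPHABET],
              tab$side_chain_carbons[["A"]])
  expect_equal(carbon_deviation(win, tab),
               unname(counts - mean(counts)))
  expect_equal(sum(carbon_deviation(win, tab)), 0, tolerance = 1e-12)
  expect_error(carbon_deviation(paste(rep("Z", 21), collapse = "")),
               "unknown residue")
})

test_that("encoded windows satisfy the one-hot and pad conventions", {
  sch <- build_schema(10)
  spec <- synthetic_spec(n_positive = 6, neg_ratio = 2, seed = 13)
  w <- generate_windows(spec)
  # force pads into the first window
  w$residues[1] <- paste0("----", substr(w$residues[1], 5, 21))
  prof <- synthesize_profiles(w, seed = 14)
  prof[[1]]$pssm[1:4, ] <- NA
  prof[[1]]$disorder[1:4] <- NA
  prof[[1]]$ss[1:4] <- NA
  prof[[1]]$acc[1:4] <- NA
  fm <- encode_windows(w, prof, schema = sch)
  expect_identical(dim(fm$values), c(18L, 727L))
  pads <- matrix(unlist(strsplit(w$residues, "")), nrow = 18,
                 byrow = TRUE) == "-"
  for (i in seq_len(nrow(w))) for (s in c(1, 4, 11, 21)) {
    ss_cols <- sch$site == s & sch$family == "SecondaryStructure"
    acc_cols <- sch$site == s & sch$family == "Accessibility"
    pssm_cols <- sch$site == s & sch$family == "PSSM"
    if (pads[i, s]) {
      expect_equal(sum(fm$values[i, ss_cols]), 0)
      expect_equal(sum(fm$values[i, acc_cols]), 0)
      expect_true(all(fm$values[i, pssm_cols] == 0))
    } else {
      expect_equal(sum(fm$values[i, ss_cols]), 1)
      expect_equal(sum(fm$values[i, acc_cols]), 1)
    }
  }
  # carbon-deviation columns sum to zero over every window
  cd <- fm$values[, sch$family == "CarbonDeviation"]
  expect_true(all(abs(rowSums(cd)) < 1e-9))
  # encoding is pure: identical inputs give identical output
  fm2 <- encode_windows(w, prof, schema = sch)
  expect_identical(fm$values, fm2$values)
})

test_that("encoder checks profile/window agreement", {
  spec <- synthetic_spec(n_positive = 3, neg_ratio = 1, seed = 5)
  w <- generate_windows(spec)
  prof <- synthesize_profiles(w, seed = 6)
  expect_error(encode_windows(w, prof[-1]), "profiles")
  short <- prof
  short[[1]]$pssm <- short[[1]]$pssm[1:10, ]
  expect_error(encode_windows(w, short), "rows")
})

test_that("feature matrices round-trip through TSV with metadata", {
  spec <- synthetic_spec(n_positive = 4, neg_ratio = 1, seed = 77)
  w <- generate_windows(spec)
  fm <- encode_windows(w, synthesize_profiles(w, seed = 78))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(path, paste0(path, ".meta.json"))))
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(unname(back$values), unname(fm$values))
  expect_identical(back$labels, fm$labels)
  expect_identical(nrow(back$schema), 727L)
})
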