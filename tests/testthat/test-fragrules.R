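test_that("neutral-loss detection finds CO2 and CO2+CH4 product ions", {
  # jaspolide-F-like side-chain acid, [M-H]- at 397.2374
  s <- msms_spectrum("jasF", 397.2374, 13.09,
                     cbind(c(353.249, 337.217), c(1000, 800)))
  hits <- detect_losses(s, list("CO2", c("CO2", "CH4")))
  expect_true(all(hits$matched))
  expect_equal(hits$observed_mz, c(353.249, 337.217))
  expect_true(all(abs(hits$error_da) <= 0.02))

  empty <- msms_spectrum("e", 397.2374, 13, matrix(numeric(0), ncol = 2))
  expect_false(any(detect_losses(empty, list("CO2"))$matched))

  off <- msms_spectrum("off", 397.2374, 13, cbind(353.30, 1000))
  expect_false(detect_losses(off, list("CO2"), tol = 0.02)$matched[1])
})

test_that("nominal ion-series rules agree with formula arithmetic", {
  expect_equal(nominal_mass(anion_mz("C8H12NO5")), 202L)
  expect_equal(nominal_mass(anion_mz("C10H16NO7")), 262L)
  expect_equal(nominal_mass(anion_mz("C6H12O9P")), 259L)
  expect_equal(nominal_mass(anion_mz("C6H10O8P")), 241L)
  expect_equal(nominal_mass(anion_mz("C6H8O7P")), 223L)
  expect_equal(nominal_mass(anion_mz("C20H29O2")), 301L)
  expect_equal(nominal_mass(anion_mz("C19H25O2")), 285L)
  expect_equal(nominal_mass(anion_mz("C19H25O")), 269L)
  expect_equal(nominal_mass(anion_mz("C16H23O2")), 247L)
  expect_equal(nominal_mass(anion_mz("C15H19O2")), 231L)
})

test_that("classification reproduces the archetypal class signatures", {
  # RAA-type: CO2 / CO2+CH4 losses plus the 301/285/261/245/229 core series
  raa <- raa_like_spectrum()
  top <- classify(raa)$hypotheses
  expect_setequal(top$class_id[top$score == max(top$score)],
                  c("SC_ACID", "CORE_RAA"))

  # jaspiferal-type 3-OH-4-COOH core: dominated by the CO2+H2O loss, no
  # CO2+CH4, with the 269/257/215/183 series
  r798 <- msms_spectrum(
    "R798", 439.249, 10.98,
    cbind(c(421.238, 411.254, 395.259, 377.249, 343.207,
            269.190, 257.190, 215.143, 183.080),
          c(400, 100, 300, 900, 1000, 550, 500, 450, 400)))
  hyp <- classify(r798)$hypotheses
  expect_equal(hyp$class_id[1], "CORE_3OH_4COOH")
  expect_false("SC_ACID" %in% hyp$class_id)

  empty <- msms_spectrum("none", 400, 10, matrix(numeric(0), ncol = 2))
  expect_equal(classify(empty)$hypotheses$class_id, "UNCLASSIFIED")
})

test_that("scores grow monotonically with evidence and requireds are hard", {
  raa <- raa_like_spectrum()
  base <- classify(raa)$hypotheses
  # adding an unrelated peak never lowers any class score
  more <- msms_spectrum(
    "RAA+", raa$precursor_mz, raa$rt,
    rbind(raa$peaks, c(350.555, 500)))
  grown <- classify(more)$hypotheses
  for (cid in base$class_id) {
    expect_gte(grown$score[grown$class_id == cid],
               base$score[base$class_id == cid])
  }
  # removing the required [M-H-CO2]- peak zeroes the side-chain-acid class
  stripped <- msms_spectrum("RAA-", raa$precursor_mz, raa$rt,
                            raa$peaks[-7, , drop = FALSE])  # drop 419.296
  expect_false("SC_ACID" %in% classify(stripped)$hypotheses$class_id)
})

test_that("annotation evidence replays onto real spectrum peaks", {
  corp <- generate_corpus(corpus_config(rng_seed = 3))
  rules <- load_class_rules()
  for (s in corp$spectra[seq(1, length(corp$spectra), by = 4)]) {
    hyp <- classify(s, rules = rules)$hypotheses
    ev <- gsub("\\([^)]*\\)", "", hyp$evidence)  # drop error annotations
    mzs <- as.numeric(unlist(regmatches(ev, gregexpr("[0-9]{2,4}\\.[0-9]+", ev))))
    for (m in mzs) {
      expect_true(any(abs(s$peaks[, "mz"] - m) < 0.02 + 1e-4),
                  label = paste("evidence m/z", m, "in", s$feature_id))
    }
  }
})

test_that("the anion nitrogen rule reads parity from nominal mass", {
  p <- nitrogen_parity(462.23)
  expect_equal(p$parity, "even")
  expect_true(p$n_odd_hint)
  expect_equal(nominal_mass(mz_deprotonated("C22H33NO5")), 390L)  # even

  q <- nitrogen_parity(463.2854)
  expect_equal(q$parity, "odd")
  expect_false(q$n_odd_hint)

  expect_warning(nitrogen_parity(0.4), "not meaningful")
})

test_that("analog pairing types acetylation, reduction and isomerism", {
  feats <- data.frame(
    feature_id = c("RAA", "stellettinH", "jaspolideF", "R42", "17Z-RAA"),
    formula = c("C30H40O4", "C32H44O5", "C25H34O4", "C25H36O4", "C30H40O4"),
    rt = c(16.87, 20.03, 13.09, 12.33, 17.27))
  rel <- pair_analogs(feats)
  get <- function(a, b) rel$relation[rel$id_a == a & rel$id_b == b]
  expect_equal(get("RAA", "stellettinH"), "ACETYL_OF_KETO")
  expect_equal(get("jaspolideF", "R42"), "DIHYDRO")
  expect_equal(get("RAA", "17Z-RAA"), "ISOMER_OF")

  dup <- feats[c(1, 1), ]
  dup$feature_id <- c("x", "x2")
  expect_equal(nrow(pair_analogs(dup[1, ])), 0)  # self-pairs excluded
})

test_that("rule files validate weights and exclusivity", {
  rules <- load_class_rules()
  expect_true(all(c("SC_ACID", "CORE_3OH_4COOH", "GLYCOSIDE", "LYSO_PI",
                    "NITROGENOUS", "CORE_RAA") %in% names(rules)))
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"classes":[{"class_id":"X","rules":[
    {"label":"l","type":"loss","chain":["CO2"],"weight":0.4}]}]}', bad)
  expect_error(load_class_rules(bad), "sum to")
})
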