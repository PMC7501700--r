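table2 <- function() utils::read.csv(table2_path(), stringsAsFactors = FALSE)

table2_enrichment <- function(df) {
  data.frame(compound_id = as.character(df$compound_id), q = df$q_value,
             stringsAsFactors = FALSE)
}

test_that("Rule-of-Five gate is strict and distinguishes missing data", {
  expect_true(lipinski_pass(136.2, 1.71, 0, 2))    # tetramethylpyrazine
  expect_true(lipinski_pass(224.26, 1.04, 2, 4))   # senkyunolide I
  # boundaries are strict, exactly as stated
  expect_false(lipinski_pass(500, 0, 0, 0))
  expect_false(lipinski_pass(100, 5, 0, 0))
  expect_false(lipinski_pass(100, 0, 5, 0))
  expect_false(lipinski_pass(100, 0, 0, 10))
  # missing field: ineligible, not fail and not pass
  expect_true(is.na(lipinski_pass(100, NA, 0, 0)))
})

test_that("HIA/BBB gate is boundary-inclusive", {
  expect_true(admet_gate(0.94, 0.81, 0.5))
  expect_true(admet_gate(0.5, 0.9, 0.5))
  expect_false(admet_gate(0.49, 0.99, 0.5))
  expect_true(is.na(admet_gate(NA, 0.9, 0.5)))
})

test_that("the four-step screen retains the nine benchmark ingredients and
           audits every gate", {
  df <- table2()
  compounds <- data.frame(compound_id = as.character(df$compound_id),
                          name = df$name, mw = df$mw, alogp = df$alogp,
                          hbd = df$hbd, hba = df$hba,
                          hia_prob = df$hia_prob, bbb_prob = df$bbb_prob,
                          stringsAsFactors = FALSE)
  enr <- table2_enrichment(df)
  rep <- four_step_screen(compounds$compound_id, compounds, enr)
  expect_equal(nrow(rep), nrow(compounds))   # no silent drops
  expect_true(all(rep$retained))
  expect_equal(sum(rep$retained), 9)

  # dropping one id from the main components flips only step 1
  rep2 <- four_step_screen(setdiff(compounds$compound_id, "370"),
                           compounds, enr)
  gal <- rep2[rep2$compound_id == "370", ]
  expect_false(gal$step1_main_component)
  expect_false(gal$retained)
  expect_true(gal$step2_ro5 && gal$step3_admet && gal$step4_enrichment)

  # a weak enrichment q fails only step 4
  enr3 <- enr; enr3$q[enr3$compound_id == "14296"] <- 0.2
  rep3 <- four_step_screen(compounds$compound_id, compounds, enr3)
  tmp <- rep3[rep3$compound_id == "14296", ]
  expect_false(tmp$step4_enrichment)
  expect_false(tmp$retained)

  # main component missing from the table: warning, excluded
  expect_warning(four_step_screen(c(compounds$compound_id, "404404"),
                                  compounds, enr),
                 "404404")
})

test_that("missing physchem or ADMET data is ineligible, never retained", {
  compounds <- data.frame(
    compound_id = c("ok", "nochem", "noadmet"),
    name = c("ok", "nochem", "noadmet"),
    mw = c(200, NA, 200), alogp = c(1, 1, 1),
    hbd = c(0, 0, 0), hba = c(2, 2, 2),
    hia_prob = c(0.9, 0.9, NA), bbb_prob = c(0.9, 0.9, 0.9),
    stringsAsFactors = FALSE)
  enr <- data.frame(compound_id = compounds$compound_id, q = 0.01,
                    stringsAsFactors = FALSE)
  rep <- four_step_screen(compounds$compound_id, compounds, enr)
  expect_equal(rep$retained, c(TRUE, FALSE, FALSE))
  expect_true(is.na(rep$step2_ro5[2]))
  expect_true(is.na(rep$step3_admet[3]))
})

random_screen_inputs <- function(seed) {
  set.seed(seed)
  n <- 40
  compounds <- data.frame(
    compound_id = paste0("c", seq_len(n)), name = paste0("c", seq_len(n)),
    mw = runif(n, 100, 700), alogp = runif(n, -1, 7),
    hbd = rpois(n, 3), hba = rpois(n, 6),
    hia_prob = runif(n), bbb_prob = runif(n),
    stringsAsFactors = FALSE)
  enr <- data.frame(compound_id = compounds$compound_id,
                    q = runif(n, 0, 0.2), stringsAsFactors = FALSE)
  list(compounds = compounds, enr = enr,
       mc = sample(compounds$compound_id, 30))
}

test_that("tightening any threshold never enlarges the retained set", {
  for (seed in 1:10) {
    inp <- random_screen_inputs(seed)
    base <- four_step_screen(inp$mc, inp$compounds, inp$enr,
                             admet_threshold = 0.5, q_star = 0.05)
    tighter_admet <- four_step_screen(inp$mc, inp$compounds, inp$enr,
                                      admet_threshold = 0.7, q_star = 0.05)
    tighter_q <- four_step_screen(inp$mc, inp$compounds, inp$enr,
                                  admet_threshold = 0.5, q_star = 0.01)
    fewer_mc <- four_step_screen(inp$mc[1:15], inp$compounds, inp$enr,
                                 admet_threshold = 0.5, q_star = 0.05)
    for (t in list(tighter_admet, tighter_q, fewer_mc))
      expect_true(all(attr(t, "retained_ids") %in%
                        attr(base, "retained_ids")))
  }
})

test_that("the gates are a pure conjunction: input order is immaterial", {
  inp <- random_screen_inputs(123)
  rep1 <- four_step_screen(inp$mc, inp$compounds, inp$enr)
  perm <- sample.int(nrow(inp$compounds))
  rep2 <- four_step_screen(rev(inp$mc), inp$compounds[perm, ], inp$enr)
  expect_setequal(attr(rep1, "retained_ids"), attr(rep2, "retained_ids"))
  expect_equal(rep1$retained,
               rep1$step1_main_component &
                 !is.na(rep1$step2_ro5) & rep1$step2_ro5 &
                 !is.na(rep1$step3_admet) & rep1$step3_admet &
                 !is.na(rep1$step4_enrichment) & rep1$step4_enrichment)
})
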