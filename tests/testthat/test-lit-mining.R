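fixture_corpus <- function() {
  # 10 documents; A in 4, B in 3, A&B in 2
  term_incidence(list(
    d01 = c("A", "B", "x"), d02 = c("A", "B"), d03 = c("A", "y"),
    d04 = c("A"), d05 = c("B"), d06 = c("x", "y"), d07 = "x",
    d08 = "y", d09 = c("x", "z"), d10 = "z"))
}

test_that("item extraction honours subheading allowlist and gene matching", {
  records <- list(
    list(id = "p1", mesh = c("Insulin/metabolism", "Insulin/history"),
         text = "IL6R is discussed, as is ILL6R."),
    list(id = "p2", mesh = "Ovary/immunology", text = "nothing here"),
    list(mesh = "Glucose/metabolism", text = "no id"))
  expect_warning(
    inc <- extract_items(records, gene_symbols = c("IL6R", "CASR")),
    "without id")
  expect_setequal(inc$p1, c("Insulin", "IL6R"))
  expect_setequal(inc$p2, "Ovary")
  expect_length(inc, 2)
})

test_that("corpus partition follows item membership", {
  inc <- term_incidence(list(d1 = c("CASR", "Ovulation"),
                             d2 = c("IL6R", "CASR"),
                             d3 = "Ovulation"))
  parts <- partition_corpus(inc, ha_genes = "CASR", na_genes = "IL6R")
  expect_setequal(names(parts$ha), c("d1", "d2"))
  expect_setequal(names(parts$na), "d2")
})

test_that("co-occurrence counting matches set enumeration", {
  inc <- fixture_corpus()
  expect_equal(cooccurrence_count(inc, "A", "B"), 2L)
  expect_equal(cooccurrence_count(inc, "a", "b"), 2L)  # case-insensitive
  expect_equal(cooccurrence_count(inc, "A", "A"), 4L)  # idempotent
  expect_equal(cooccurrence_count(inc, "A", "missing"), 0L)
  withr::with_seed(101, {
    docs <- lapply(1:30, function(i)
      sample(letters[1:6], sample(0:4, 1)))
    names(docs) <- sprintf("r%02d", 1:30)
  })
  rinc <- term_incidence(docs)
  for (pair in list(c("a", "b"), c("c", "f"), c("e", "e")))
    expect_equal(cooccurrence_count(rinc, pair[1], pair[2]),
                 oracle_cooccur(rinc, pair[1], pair[2]))
})

test_that("two-element rules compute confidence and normalized support", {
  rules <- lit_rules_2(fixture_corpus(), items = c("A", "B"),
                       conf_cut = 0, supp_cut = 0)
  ab <- rules[rules$lhs == "A" & rules$rhs == "B", ]
  expect_equal(ab$confidence, 0.5)   # 2 of 4 A-documents contain B
  expect_equal(ab$support, 0.7)      # (4 + 3) / 10
  ba <- rules[rules$lhs == "B" & rules$rhs == "A", ]
  expect_equal(ba$confidence, 2 / 3)
  raw <- lit_rules_2(fixture_corpus(), items = c("A", "B"), conf_cut = 0,
                     supp_cut = 0, normalize_support = FALSE)
  expect_equal(raw$support[raw$lhs == "A"], 7)
  # containment gives confidence 1
  inc2 <- term_incidence(list(d1 = c("p", "q"), d2 = c("p", "q"),
                              d3 = "q"))
  r2 <- lit_rules_2(inc2, items = c("p", "q"), conf_cut = 0, supp_cut = 0)
  expect_equal(r2$confidence[r2$lhs == "p"], 1)
})

test_that("rule cuts are strict and confidence times n(A) is an integer", {
  # confidence exactly 0.1 (1 of 10) is rejected; 0.2 is kept
  docs <- c(lapply(1:10, function(i)
    if (i <= 1) c("A", "B") else "A"),
    list(extra = "B"))
  names(docs) <- c(sprintf("d%02d", 1:10), "d11")
  inc <- term_incidence(docs)
  r <- lit_rules_2(inc, items = c("A", "B"), conf_cut = 0.1, supp_cut = 0)
  expect_false(any(r$lhs == "A"))
  docs2 <- docs; docs2[[2]] <- c("A", "B")
  r2 <- lit_rules_2(term_incidence(docs2), items = c("A", "B"),
                    conf_cut = 0.1, supp_cut = 0)
  expect_true(any(r2$lhs == "A"))
  # support exactly 0.001 rejected, above kept
  big <- c(list(d0 = c("A", "B")),
           lapply(1:1999, function(i) "filler"))
  names(big) <- c("d0", sprintf("f%04d", 1:1999))
  r3 <- lit_rules_2(term_incidence(big), items = c("A", "B"),
                    conf_cut = 0, supp_cut = 0.001)
  expect_equal(nrow(r3), 0L)          # support (1+1)/2000 = 0.001 exactly
  r4 <- lit_rules_2(term_incidence(big[1:1000]), items = c("A", "B"),
                    conf_cut = 0, supp_cut = 0.001)
  expect_equal(nrow(r4), 2L)          # (1+1)/1000 = 0.002 > 0.001
  # conf * |docs(A)| recovers the intersection count exactly
  all_r <- lit_rules_2(fixture_corpus(), conf_cut = 0, supp_cut = 0)
  n_docs <- vapply(all_r$lhs, function(it)
    cooccurrence_count(fixture_corpus(), it, it), integer(1))
  expect_true(all(abs(all_r$confidence * n_docs -
                        round(all_r$confidence * n_docs)) < 1e-9))
})

test_that("duplicating every document leaves confidences and support unchanged", {
  inc <- fixture_corpus()
  doubled <- term_incidence(stats::setNames(c(unclass(inc), unclass(inc)),
                                            c(names(inc),
                                              paste0(names(inc), "_dup"))))
  r1 <- lit_rules_2(inc, conf_cut = 0, supp_cut = 0)
  r2 <- lit_rules_2(doubled, conf_cut = 0, supp_cut = 0)
  key <- function(r) r[order(r$lhs, r$rhs), ]
  expect_equal(key(r1)$confidence, key(r2)$confidence)
  expect_equal(key(r1)$support, key(r2)$support)
})

test_that("three-element chaining multiplies confidences and prunes", {
  rules2 <- data.frame(lhs = c("A", "B", "C", "B"),
                       rhs = c("B", "C", "D", "A"),
                       confidence = c(0.5, 0.4, 0.3, 0.2),
                       support = 0.5, stringsAsFactors = FALSE)
  r3 <- extend_rules_3(rules2, conf_cut = 0.1)
  abc <- r3[r3$e1 == "A" & r3$e3 == "C", ]
  expect_equal(abc$confidence, 0.2)          # 0.5 * 0.4, retained
  expect_false(any(r3$e1 == "A" & r3$e3 == "D"))  # would need B->C->D
  bcd <- r3[r3$e1 == "B" & r3$e3 == "D", ]
  expect_equal(bcd$confidence, 0.4 * 0.3)
  # 0.2 x 0.3 = 0.06 < 0.1 is dropped
  weak <- data.frame(lhs = c("X", "Y"), rhs = c("Y", "Z"),
                     confidence = c(0.2, 0.3), support = 0.5)
  expect_equal(nrow(extend_rules_3(weak, conf_cut = 0.1)), 0L)
  # chained confidence never exceeds either constituent
  withr::with_seed(103, {
    rnd <- data.frame(lhs = sample(LETTERS[1:6], 20, TRUE),
                      rhs = sample(LETTERS[1:6], 20, TRUE),
                      confidence = runif(20), support = 1)
    rnd <- rnd[rnd$lhs != rnd$rhs, ]
  })
  r <- extend_rules_3(rnd, conf_cut = 0)
  expect_true(all(r$confidence <= pmin(r$conf12, r$conf23) + 1e-12))
  # elements of a chain are pairwise distinct
  expect_true(all(r$e1 != r$e3 & r$e1 != r$e2 & r$e2 != r$e3))
})

test_that("terminal filtering is positional on the third element", {
  r3 <- data.frame(e1 = c("A", "A", "B"),
                   e2 = c("B", "female infertility", "C"),
                   e3 = c("female infertility", "C", "other"),
                   confidence = 0.3, conf12 = 0.5, conf23 = 0.6)
  out <- terminal_filter(r3)
  expect_equal(nrow(out), 1L)
  expect_equal(out$e1, "A")
  expect_equal(nrow(terminal_filter(r3[0, ])), 0L)
})
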