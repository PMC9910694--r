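test_that("code-pattern retrieval on the printed six-record table", {
  cat6 <- table4_catalog()
  # myocarditis x spontaneous: two records differing only in attributes
  res <- search_by_code_pattern(cat6, query_pattern(a = "0101", c = "01"))
  expect_identical(res$candidate_count, 2L)
  expect_identical(res$record_ids, c("t4r1", "t4r2"))
  # unconstrained pattern returns everything
  expect_identical(search_by_code_pattern(cat6, query_pattern())$candidate_count,
                   6L)
  # fully literal pattern pins the unique record
  res <- search_by_code_pattern(cat6, query_pattern(a = "0101", b = "1111001",
                                                    c = "01", d = "122"))
  expect_identical(res$record_ids, "t4r1")
  # per-digit wildcards
  res <- search_by_code_pattern(cat6, query_pattern(d = "3??"))
  expect_identical(res$record_ids, c("t4r2", "t4r4", "t4r6"))
  expect_error(query_pattern(a = "01"), "width")
  expect_error(query_pattern(a = "01x1"), "digits")
})

test_that("pattern search agrees with the per-record regex-scan oracle", {
  catalog <- generate_catalog(fixture_reg(),
                              generator_config(total_records = 10000,
                                               seed = 202))
  set.seed(7)
  for (k in 1:12) {
    # derive a pattern from a random record, wildcarding random positions
    code <- catalog$code[sample(nrow(catalog), 1)]
    segs <- list(a = substr(code, 9, 12), b = substr(code, 14, 20),
                 c = substr(code, 22, 23), d = substr(code, 25, 27))
    for (s in names(segs)) {
      if (runif(1) < 0.3) {
        segs[[s]] <- "*"
      } else {
        n <- nchar(segs[[s]])
        mask <- runif(n) < 0.5
        chars <- strsplit(segs[[s]], "")[[1]]
        chars[mask] <- "?"
        segs[[s]] <- paste(chars, collapse = "")
      }
    }
    got <- search_by_code_pattern(catalog,
                                  query_pattern(segs$a, segs$b, segs$c, segs$d))
    want <- scan_oracle(catalog, segs$a, segs$b, segs$c, segs$d)
    expect_identical(got$record_ids, want)
    expect_identical(got$candidate_count, length(want))
  }
})

test_that("refining a pattern with a literal digit never grows the result", {
  catalog <- generate_catalog(fixture_reg(),
                              generator_config(total_records = 2000,
                                               seed = 77))
  set.seed(8)
  for (k in 1:20) {
    code <- catalog$code[sample(nrow(catalog), 1)]
    a <- substr(code, 9, 12)
    loose <- paste0(substr(a, 1, 2), "??")
    tight <- paste0(substr(a, 1, 3), "?")
    n_loose <- search_by_code_pattern(catalog,
                                      query_pattern(a = loose))$candidate_count
    n_tight <- search_by_code_pattern(catalog,
                                      query_pattern(a = tight))$candidate_count
    expect_lte(n_tight, n_loose)
  }
})

test_that("neighbor expansion equals the brute-force scan and drops the base", {
  cat6 <- table4_catalog()
  base <- "CSTR09:A0101B1111001C01D122"
  # varying cooperation and sharing reaches the D312 sibling
  res <- neighbor_expansion(cat6, base, c("D.cooperation", "D.sharing"))
  expect_identical(res$record_ids, "t4r2")
  expect_identical(scan_oracle(cat6, a = "0101", b = "1111001", c = "01",
                               d = "??2", exclude_code = base), "t4r2")
  # varying cooperation and preservation reaches nothing in this table
  res <- neighbor_expansion(cat6, base, c("D.cooperation", "D.preservation"))
  expect_identical(res$candidate_count, 0L)
  # varying the modeling category from a C01 base finds records differing
  # only in C (none here: the C02 rows carry a different disease)
  res <- neighbor_expansion(cat6, base, "C.category")
  expect_identical(res$candidate_count, 0L)
  # single-record catalog: expansion of its own code finds nothing
  cat1 <- amr_catalog(data.frame(record_id = "only", code = base))
  expect_identical(neighbor_expansion(cat1, base,
                                      "A.intermediate")$candidate_count, 0L)
  expect_error(neighbor_expansion(cat6, base, character(0)), "nonempty")
  expect_error(neighbor_expansion(cat6, base, "E.major"), "unknown layer")
  expect_error(neighbor_expansion(cat6, "CSTR09:A01", "C.category"),
               "invalid base")
})

test_that("neighbor expansion matches the scan oracle on a synthetic catalog", {
  catalog <- generate_catalog(fixture_reg(),
                              generator_config(total_records = 3000,
                                               seed = 31))
  base <- catalog$code[17]
  segs <- list(a = substr(base, 9, 12), b = substr(base, 14, 20),
               c = substr(base, 22, 23), d = substr(base, 25, 27))
  res <- neighbor_expansion(catalog, base, c("A.intermediate", "B.strain"))
  want <- scan_oracle(catalog,
                      a = paste0(substr(segs$a, 1, 2), "??"), b = paste0(substr(segs$b, 1, 4), "???"),
                      c = segs$c, d = segs$d, exclude_code = base)
  expect_identical(res$record_ids, want)
})

test_that("keyword retrieval ANDs fields and composes as set intersection", {
  catalog <- generate_catalog(fixture_reg(),
                              generator_config(total_records = 500,
                                               seed = 12))
  r1 <- keyword_search(catalog, list(name = "mouse"))
  r2 <- keyword_search(catalog, list(preservation = "frozen"))
  r12 <- keyword_search(catalog, list(name = "mouse", preservation = "frozen"))
  expect_setequal(r12$record_ids, intersect(r1$record_ids, r2$record_ids))
  expect_identical(r12$candidate_count, length(intersect(r1$record_ids,
                                                         r2$record_ids)))
  # partial fields match substrings, exact fields whole values
  expect_identical(keyword_search(catalog,
                                  list(preservation = "froz"))$candidate_count,
                   0L)
  expect_gt(keyword_search(catalog, list(name = "mous"))$candidate_count, 0L)
  expect_error(keyword_search(catalog, list(strain = "C57")), "unknown field")
  expect_error(keyword_search(catalog, list("SARS")), "named")
  # empty catalog yields zero candidates
  empty <- amr_catalog(data.frame(record_id = character(),
                                  code = character()))
  expect_identical(keyword_search(empty, list(name = "SARS"))$candidate_count,
                   0L)
})

test_that("records in the SARS cell are retrievable by the SARS keyword", {
  catalog <- generate_catalog(fixture_reg(),
                              generator_config(total_records = 865, seed = 4))
  hits <- keyword_search(catalog, list(name = "SARS"))
  in_cell <- grepl("^CSTR09:A0312", catalog$code)
  expect_identical(sort(hits$record_ids), sort(catalog$record_id[in_cell]))
  expect_gt(hits$candidate_count, 0L)
})

test_that("benchmark: literal patterns one-shot unique codes; keyword baseline trails", {
  cat6 <- table4_catalog()  # six records, all codes distinct
  qs <- lapply(seq_len(nrow(cat6)), function(i) {
    code <- cat6$code[i]
    list(target_id = cat6$record_id[i],
         terms = list(name = "model"),
         pattern = query_pattern(substr(code, 9, 12), substr(code, 14, 20),
                                 substr(code, 22, 23), substr(code, 25, 27)))
  })
  rep <- benchmark_one_shot(cat6, qs)
  expect_identical(rep$new_method$one_shot_rate, 1)
  expect_identical(rep$new_method$mean_candidates, 1)
  expect_identical(rep$new_method$max_candidates, 1)

  # default seeded synthetic benchmark: the keyword baseline returns strictly
  # larger candidate lists on average
  catalog <- generate_catalog(fixture_reg(), generator_config(seed = 1))
  report <- benchmark_one_shot(catalog, make_query_set(catalog, 60, seed = 2))
  expect_gt(report$old_method$mean_candidates,
            report$new_method$mean_candidates)
  expect_gte(report$new_method$one_shot_rate, report$old_method$one_shot_rate)

  # empty query set: rates are undefined, not fabricated
  empty <- benchmark_one_shot(cat6, list())
  expect_identical(empty$n_queries, 0L)
  expect_true(is.na(empty$old_method$one_shot_rate))
  expect_error(benchmark_one_shot(cat6, list(list(target_id = "nope",
                                                  terms = list(name = "x"),
                                                  pattern = query_pattern()))),
               "unknown target")
})
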