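# Shared fixtures: the six-row cardiovascular coding table and independent
# scan oracles used to cross-check the retrieval engine.

fixture_reg <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- amr_fixture_registry()
    cache
  }
})

# The printed six-row cardiovascular coding table: code plus the
# classification/attribute gloss it pairs with.
table4_rows <- function() {
  list(
    list(code = "CSTR09:A0101B1111001C01D122",
         disease = c("cardiovascular disease", "myocarditis"),
         species = c("laboratory animal", "mouse", "BALB/c"),
         modeling = "spontaneous",
         cooperation = "independence", sharing = "free", preservation = "frozen"),
    list(code = "CSTR09:A0101B1111001C01D312",
         disease = c("cardiovascular disease", "myocarditis"),
         species = c("laboratory animal", "mouse", "BALB/c"),
         modeling = "spontaneous",
         cooperation = "outsourcing", sharing = "paid", preservation = "frozen"),
    list(code = "CSTR09:A0102B1127001C01D121",
         disease = c("cardiovascular disease", "pericarditis"),
         species = c("laboratory animal", "rabbit", "New Zealand"),
         modeling = "spontaneous",
         cooperation = "independence", sharing = "free", preservation = "live"),
    list(code = "CSTR09:A0102B1127001C01D322",
         disease = c("cardiovascular disease", "pericarditis"),
         species = c("laboratory animal", "rabbit", "New Zealand"),
         modeling = "spontaneous",
         cooperation = "outsourcing", sharing = "free", preservation = "frozen"),
    list(code = "CSTR09:A0103B1111001C02D121",
         disease = c("cardiovascular disease", "myocardial infarction"),
         species = c("laboratory animal", "mouse", "BALB/c"),
         modeling = "induced",
         cooperation = "independence", sharing = "free", preservation = "live"),
    list(code = "CSTR09:A0103B1111001C02D311",
         disease = c("cardiovascular disease", "myocardial infarction"),
         species = c("laboratory animal", "mouse", "BALB/c"),
         modeling = "induced",
         cooperation = "outsourcing", sharing = "paid", preservation = "live")
  )
}

table4_catalog <- function() {
  rows <- table4_rows()
  amr_catalog(data.frame(
    record_id = sprintf("t4r%d", seq_along(rows)),
    code = vapply(rows, `[[`, character(1), "code"),
    stringsAsFactors = FALSE))
}

# Independent retrieval oracle: per-record regex scan. Patterns are turned
# into a regular expression ('?' -> [0-9], '*' -> [0-9]{width}); each record
# is tested one by one, then ordered by (code, record_id).
scan_oracle <- function(catalog, a = "*", b = "*", c = "*", d = "*",
                        profile = "paper", exclude_code = NULL) {
  widths <- c(A = 4L, B = 7L, C = 2L, D = 3L)
  if (profile == "extended") widths <- c(A = 6L, B = 7L, C = 4L, D = 3L)
  seg_rx <- function(p, w) {
    if (p == "*") sprintf("[0-9]{%d}", w) else gsub("?", "[0-9]", p, fixed = TRUE)
  }
  rx <- paste0("^CSTR09:",
               "A", seg_rx(a, widths["A"]), "B", seg_rx(b, widths["B"]),
               "C", seg_rx(c, widths["C"]), "D", seg_rx(d, widths["D"]), "$")
  hit <- vapply(seq_len(nrow(catalog)), function(i) {
    grepl(rx, catalog$code[i]) &&
      (is.null(exclude_code) || catalog$code[i] != exclude_code)
  }, logical(1))
  ids <- catalog$record_id[hit]
  ids[order(catalog$code[hit], ids, method = "radix")]
}
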