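pina_file <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(paste("ID(s) interactor A", "ID(s) interactor B", "Alt A",
                     "Alt B", "Publication Identifier(s)", sep = "\t"),
               lines), tf)
  tf
}

test_that("PINA-style lines yield records with stripped prefixes and PubMed IDs", {
  tf <- pina_file(c(
    "uniprotkb:P04637\tuniprotkb:Q13625\t-\t-\tpubmed:12345678",
    "uniprotkb:P04637\tuniprotkb:P60484\t-\t-\tpubmed:222|pubmed:111"
  ))
  rec <- parse_pina(tf)
  expect_identical(rec$id_a, c("P04637", "P04637"))
  expect_identical(rec$id_b, c("Q13625", "P60484"))
  expect_identical(unique(rec$source_db), "PINA")
  expect_identical(rec$pmids[[1]], 12345678L)
  expect_identical(rec$pmids[[2]], c(111L, 222L))
  expect_true(all(is.na(rec$string_score)))
  expect_identical(attr(rec, "n_skipped"), 0L)
})

test_that("malformed lines are skipped and counted, not fatal", {
  tf <- pina_file(c(
    "uniprotkb:P04637\tuniprotkb:Q13625\t-\t-\tpubmed:1",
    "uniprotkb:P04637",             # missing interactor B
    "uniprotkb:P04637\t-\t-\t-\t-"  # empty interactor B
  ))
  rec <- parse_pina(tf)
  expect_identical(nrow(rec), 1L)
  expect_identical(attr(rec, "n_skipped"), 2L)
})

test_that("a file with no parseable lines is a format error, a missing file an I/O error", {
  tf <- pina_file("only-one-field")
  expect_error(parse_pina(tf), class = "ppipath_format_error")
  expect_error(parse_pina(tempfile()), class = "ppipath_io_error")
})

test_that("iRefIndex dialect parses multi-PubMed fields at its column position", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#uidA\tuidB\taltA\taltB\taliasA\taliasB\tpmids\tmethod\tsourcedb",
    "uniprotkb:P1\tuniprotkb:P2\t-\t-\t-\t-\tpubmed:10|pubmed:20\tMI:0018\tintact"
  ), tf)
  rec <- parse_irefindex(tf)
  expect_identical(rec$source_db, "iRefIndex")
  expect_identical(rec$pmids[[1]], c(10L, 20L))
})

string_files <- function(rows, aliases) {
  links <- tempfile(); alias <- tempfile()
  writeLines(c("protein1 protein2 combined_score", rows), links)
  writeLines(c("#string_protein_id\talias\tsource", aliases), alias)
  list(links = links, alias = alias)
}

test_that("STRING threshold keeps score 700 and drops 699 at the default", {
  f <- string_files(
    c("9606.ENSP1 9606.ENSP2 700", "9606.ENSP1 9606.ENSP3 699"),
    c("9606.ENSP1\tTP53\tx", "9606.ENSP2\tPTEN\tx", "9606.ENSP3\tMAGI1\tx")
  )
  rec <- parse_string(f$links, f$alias)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$string_score, 700L)
  expect_identical(rec$id_a, "TP53")
  expect_identical(rec$id_b, "PTEN")
  all_rec <- parse_string(f$links, f$alias, score_threshold = 0L)
  expect_identical(nrow(all_rec), 2L)
})

test_that("STRING rows without an alias are dropped and counted", {
  f <- string_files(
    c("9606.ENSP1 9606.NOALIAS 900", "9606.ENSP1 9606.ENSP2 900"),
    c("9606.ENSP1\tTP53\tx", "9606.ENSP2\tPTEN\tx")
  )
  rec <- parse_string(f$links, f$alias)
  expect_identical(nrow(rec), 1L)
  expect_identical(attr(rec, "n_unaliased"), 1L)
  expect_error(parse_string(f$links, tempfile()), class = "ppipath_io_error")
})

test_that("raising the STRING threshold always emits a subset of records", {
  b <- gen_random_ppi(30, 60, seed = 11,
                      source_mix = c(STRING = 1), score_range = c(1L, 999L))
  key <- function(r) paste(r$id_a, r$id_b, r$string_score)
  prev <- parse_string(b$string_links_path, b$string_alias_path, 0L)
  for (thr in c(300L, 700L, 900L)) {
    cur <- parse_string(b$string_links_path, b$string_alias_path, thr)
    expect_true(all(key(cur) %in% key(prev)))
    expect_true(all(cur$string_score >= thr))
    prev <- cur
  }
})

test_that("standard table write-read is an exact identity, overrides included", {
  tbl <- tibble::tibble(
    acc_a = c("P1", "P1"), acc_b = c("P2", "P3"),
    sources = c("PINA;STRING", "iRefIndex"),
    pmids = c("111;222", ""),
    string_score = c(850L, NA), cost = c(NA, 2.5)
  )
  tf <- tempfile()
  write_standard(tbl, tf)
  expect_identical(read_standard(tf), tbl)

  empty <- tbl[0, ]
  tf2 <- tempfile()
  write_standard(empty, tf2)
  expect_identical(nrow(read_standard(tf2)), 0L)
})

test_that("standard tables are byte-stable under write-read-write", {
  tbl <- rand_table(30, 120, seed = 5, p_override = 0.2)
  tbl <- tbl[order(tbl$acc_a, tbl$acc_b, method = "radix"), ]
  f1 <- tempfile(); f2 <- tempfile()
  write_standard(tbl, f1)
  write_standard(read_standard(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("duplicate or non-canonical pairs are format errors naming the pair", {
  dup <- tibble::tibble(
    acc_a = c("P1", "P1"), acc_b = c("P2", "P2"),
    sources = "PINA", pmids = "", string_score = NA_integer_, cost = NA_real_
  )
  expect_error(write_standard(dup, tempfile()), "P1, P2",
               class = "ppipath_format_error")
  bad <- tibble::tibble(acc_a = "P9", acc_b = "P1", sources = "PINA",
                        pmids = "", string_score = NA_integer_, cost = NA_real_)
  expect_error(write_standard(bad, tempfile()), class = "ppipath_format_error")
})

test_that("fixture parser counts match the generator's bookkeeping", {
  b <- gen_random_ppi(40, 80, seed = 9)
  expect_identical(nrow(parse_pina(b$pina_path)), b$counts$pina_lines)
  expect_identical(nrow(parse_irefindex(b$iref_path)), b$counts$iref_lines)
  rec <- parse_string(b$string_links_path, b$string_alias_path, 0L)
  expect_identical(nrow(rec), b$counts$string_rows)
})
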