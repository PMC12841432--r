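test_that("canonical serialization is deterministic with sorted keys", {
  x <- list(b = 2, a = "hi", c = list(z = TRUE, y = c(1, 2, 3)), d = NULL)
  j <- canonical_json(x)
  expect_identical(j, '{"a":"hi","b":2,"c":{"y":[1,2,3],"z":true},"d":null}')
  # round trip through a parser and back is stable
  back <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  expect_identical(canonical_json(back), j)
  # full precision for doubles
  v <- list(x = 0.1 + 0.2)
  expect_identical(jsonlite::fromJSON(canonical_json(v))$x, 0.1 + 0.2)
})

test_that("classification uses strict inequality and names violations in schema order", {
  thr <- default_thresholds()
  rec <- list(sample_id = "S1", values = as.list(thr))   # all exactly at limits
  out <- classify_record(rec, thr)
  expect_equal(out$status, "compliant")
  expect_length(out$violated_indicators, 0)

  rec$values$cadmium <- thr[["cadmium"]] * 1.01
  out <- classify_record(rec, thr)
  expect_equal(out$status, "exceeding")
  expect_equal(out$violated_indicators, "cadmium")

  rec$values$ZEN <- thr[["ZEN"]] * 2
  rec$values$pesticide_residue <- thr[["pesticide_residue"]] * 3
  out <- classify_record(rec, thr)
  expect_equal(out$violated_indicators, c("pesticide_residue", "cadmium", "ZEN"))

  expect_error(classify_record(list(values = list(unknown = 1)), thr), "unknown")
})

test_that("classification agrees with an independent scan on random records", {
  tab <- generate_samples(generator_config(n_samples = 1000, seed = 31,
                                           exceedance_fraction = 0.25))
  thr <- default_thresholds()
  recs <- records_from_table(tab)
  X <- indicator_matrix(tab)
  for (i in seq_along(recs)) {
    got <- classify_record(recs[[i]], thr)$status
    want <- if (any(X[i, ] > thr[colnames(X)])) "exceeding" else "compliant"
    expect_identical(got, want)
  }
})

test_that("merkle root: identity, avalanche, hand-built two-level oracle", {
  sha_hex <- grainrisk:::.sha256_hex
  leaf <- vapply(1:4, function(i) sha_hex(charToRaw(paste0("leaf", i))),
                 character(1))
  expect_identical(merkle_root(leaf[1]), leaf[1])

  # hand-built two-level computation with explicit byte concatenation
  hx <- function(h) as.raw(strtoi(substring(h, seq(1, 63, 2), seq(2, 64, 2)), 16L))
  n12 <- sha_hex(c(hx(leaf[1]), hx(leaf[2])))
  n34 <- sha_hex(c(hx(leaf[3]), hx(leaf[4])))
  expect_identical(merkle_root(leaf), sha_hex(c(hx(n12), hx(n34))))

  # flipping one byte of one of 8 leaves changes the root
  leaf8 <- vapply(1:8, function(i) sha_hex(charToRaw(paste0("L", i))), character(1))
  root <- merkle_root(leaf8)
  mutated <- leaf8
  substr(mutated[5], 1, 1) <- if (substr(mutated[5], 1, 1) == "0") "1" else "0"
  expect_false(identical(merkle_root(mutated), root))

  # odd count duplicates the last node
  expect_identical(merkle_root(leaf8[1:3]),
                   merkle_root(c(leaf8[1:3], leaf8[3])))
  expect_identical(merkle_root(character(0)), sha_hex(raw(0)))
  expect_error(merkle_root("zz"), "malformed")
})

make_test_ledger <- function(n_blocks = 3, per_block = 4, seed = 7,
                             frac = 1) {
  set.seed(seed)
  state <- ledger_init()
  tab <- generate_samples(generator_config(n_samples = n_blocks * per_block,
                                           seed = seed,
                                           exceedance_fraction = frac))
  recs <- records_from_table(tab, predictions = runif(nrow(tab)))
  recs <- lapply(recs, classify_record, thresholds = state$thresholds)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * per_block + 1):(b * per_block)
    state <- append_block(state, recs[idx])
  }
  state
}

test_that("append_block builds a linked chain from genesis", {
  state <- make_test_ledger(3, 4)
  expect_length(state$chain, 3)
  expect_identical(state$chain[[1]]$header$previous_hash, strrep("0", 64))
  expect_equal(state$chain[[1]]$header$index, 0)
  expect_identical(state$chain[[2]]$header$previous_hash,
                   state$chain[[1]]$block_hash)
  expect_equal(state$chain[[2]]$header$record_count, 4)
  chk <- validate_chain(state)
  expect_true(chk$valid)

  # a compliant record without prediction cannot be anchored
  bad <- list(sample_id = "X", batch_id = "B", region = "R",
              detection_date = "2020-01-01",
              values = as.list(default_thresholds() * 0.5))
  bad <- classify_record(bad, default_thresholds())
  expect_error(append_block(state, list(bad)), "compliant")
  expect_error(append_block(state, list()), "no records")
})

test_that("record serialization and hashing are byte-stable across rounds", {
  state <- make_test_ledger(1, 3, seed = 9)
  rec <- state$chain[[1]]$body[[1]]
  j1 <- canonical_json(rec)
  rec2 <- jsonlite::fromJSON(j1, simplifyVector = FALSE)
  expect_identical(canonical_json(rec2), j1)
  expect_identical(grainrisk:::.sha256_hex(charToRaw(j1)),
                   grainrisk:::.sha256_hex(charToRaw(canonical_json(rec2))))
})

test_that("single-byte mutations anywhere in a block body are detected", {
  state <- make_test_ledger(5, 4, seed = 11)
  set.seed(12)
  for (trial in 1:25) {
    mutated <- state
    bi <- sample.int(5, 1)
    ri <- sample.int(4, 1)
    rec <- mutated$chain[[bi]]$body[[ri]]
    # mutate one concentration by a tiny amount
    ind <- sample(names(rec$values), 1)
    rec$values[[ind]] <- rec$values[[ind]] * (1 + 1e-9) + 1e-12
    mutated$chain[[bi]]$body[[ri]] <- rec
    chk <- validate_chain(mutated)
    expect_false(chk$valid)
    expect_equal(chk$first_invalid, bi - 1L)
  }
})

test_that("recomputing only the mutated block's hashes still breaks linkage", {
  state <- make_test_ledger(6, 3, seed = 13)
  mutated <- state
  rec <- mutated$chain[[4]]$body[[1]]
  rec$values[[1]] <- rec$values[[1]] + 1
  # re-sign and rebuild block 4 (index 3) completely
  rec$signature <- NULL
  rec$signature <- sm2_sign(charToRaw(grainrisk:::.record_payload(rec)),
                            mutated$keys)
  mutated$chain[[4]]$body[[1]] <- rec
  leaf <- vapply(mutated$chain[[4]]$body,
                 function(r) grainrisk:::.sha256_hex(charToRaw(canonical_json(r))),
                 character(1))
  mutated$chain[[4]]$header$merkle_root <- merkle_root(leaf)
  mutated$chain[[4]]$block_hash <-
    grainrisk:::.sha256_hex(charToRaw(canonical_json(mutated$chain[[4]]$header)))
  chk <- validate_chain(mutated)
  expect_false(chk$valid)
  expect_equal(chk$first_invalid, 4L)   # block 5 (index 4) has a broken link
})

test_that("store_record routes exclusively and exhaustively", {
  set.seed(15)
  state <- ledger_init()
  tab <- generate_samples(generator_config(n_samples = 100, seed = 15,
                                           exceedance_fraction = 0.3))
  recs <- records_from_table(tab, predictions = runif(100))
  routes <- character(100)
  for (i in seq_along(recs)) {
    res <- store_record(state, recs[[i]])
    state <- res$state
    routes[i] <- res$routing
  }
  expect_equal(length(state$staged) + length(state$local_store), 100)
  state <- append_block(state)
  chk <- validate_chain(state)
  expect_true(chk$valid)
  onchain_ids <- unlist(lapply(state$chain, function(b) {
    vapply(b$body, function(r) r$sample_id, character(1))
  }))
  local <- decrypt_local_store(state)
  local_ids <- vapply(local, function(r) r$sample_id, character(1))
  expect_length(intersect(onchain_ids, local_ids), 0)
  expect_setequal(c(onchain_ids, local_ids), tab$sample_id)
  # decrypted record content matches the original serialization
  first_local_id <- local_ids[1]
  orig <- recs[[match(first_local_id, tab$sample_id)]]
  orig <- classify_record(orig, state$thresholds)
  expect_identical(canonical_json(local[[1]]), canonical_json(orig))
})

test_that("anchor-all policy sends compliant predicted records on-chain", {
  set.seed(16)
  state <- ledger_init(anchor_predictions = "all")
  rec <- list(sample_id = "S1", batch_id = "B1", region = "R1",
              detection_date = "2021-05-05",
              values = as.list(default_thresholds() * 0.1),
              prediction = list(risk_value = 0.12, risk_band = "low"))
  res <- store_record(state, rec)
  expect_equal(res$routing, "chain")
})

test_that("queries match a linear scan for all three selectors", {
  state <- make_test_ledger(4, 5, seed = 17)
  all_recs <- do.call(c, lapply(state$chain, function(b) b$body))
  # by id
  expect_length(ledger_query(state, "id", value = "NOPE"), 0)
  some_id <- all_recs[[7]]$sample_id
  hits <- ledger_query(state, "id", value = some_id)
  expect_length(hits, 1)
  expect_true(!is.null(hits[[1]]$block_index))
  # by batch, against a scan
  batches <- unique(vapply(all_recs, function(r) r$batch_id, character(1)))
  for (b in batches) {
    hits <- ledger_query(state, "batch", value = b)
    want <- sum(vapply(all_recs, function(r) identical(r$batch_id, b), logical(1)))
    expect_length(hits, want)
  }
  # by time: full span captures everything, half-open boundary excluded
  dates <- as.Date(vapply(all_recs, function(r) r$detection_date, character(1)))
  hits <- ledger_query(state, "time", start = min(dates), end = max(dates) + 1)
  expect_length(hits, length(all_recs))
  hits2 <- ledger_query(state, "time", start = min(dates), end = max(dates))
  expect_length(hits2, sum(dates < max(dates)))
  expect_error(ledger_query(state, "time", start = "2020-01-02",
                            end = "2020-01-01"), "before")
})

test_that("ledger persists to JSON lines and validates after reload", {
  state <- make_test_ledger(2, 3, seed = 19)
  path <- tempfile(fileext = ".jsonl")
  write_ledger(state, path)
  back <- read_ledger(path)
  expect_true(validate_chain(back)$valid)
  expect_equal(length(back$chain), 2)
  expect_identical(back$chain[[2]]$block_hash, state$chain[[2]]$block_hash)
  expect_equal(length(back$local_store), length(state$local_store))
})
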