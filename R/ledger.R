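# Tiered traceability ledger.
#
# Policy ("smart contract") functions are deterministic in-process R:
# classification against configured safety limits, routing (exceeding
# records and their predictions to hash-chained blocks, compliant records
# SM2-encrypted into a local store), and the three query modes. Blocks carry
# a SHA-256 Merkle root of their record hashes and link by header hash.

# ---- canonical serialization -----------------------------------------------

.json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  s <- gsub("\n", "\\\\n", s)
  s <- gsub("\r", "\\\\r", s)
  s <- gsub("\t", "\\\\t", s)
  s
}

#' Canonical JSON serialization
#'
#' Deterministic JSON used for hashing and signing ledger content: UTF-8,
#' lexicographically sorted object keys, no insignificant whitespace, numbers
#' rendered with `%.17g` (round-trip precision). Identical R objects always
#' serialize to identical bytes, across processes.
#'
#' @param x an R object made of named/unnamed lists, numbers, strings,
#'   logicals, dates and NULLs.
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (inherits(x, "Date")) return(paste0("\"", format(x, "%Y-%m-%d"), "\""))
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) {
      ord <- order(nm, method = "radix")
      parts <- vapply(ord, function(i) {
        paste0("\"", .json_escape(nm[i]), "\":", canonical_json(x[[i]]))
      }, character(1))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    return(paste0("[", paste(vapply(x, canonical_json, character(1)),
                             collapse = ","), "]"))
  }
  if (length(x) != 1) {
    return(paste0("[", paste(vapply(seq_along(x),
                                    function(i) canonical_json(x[[i]]),
                                    character(1)), collapse = ","), "]"))
  }
  if (is.character(x)) return(paste0("\"", .json_escape(x), "\""))
  if (is.logical(x)) return(if (isTRUE(x)) "true" else "false")
  if (is.numeric(x)) {
    if (!is.finite(x)) stop("canonical_json: non-finite number")
    if (x == round(x) && abs(x) < 2^53) {
      return(sprintf("%.0f", x))
    }
    return(sprintf("%.17g", x))
  }
  stop("canonical_json: unsupported type ", class(x)[1])
}

# ---- detection records -----------------------------------------------------

#' Classify a detection record against safety limits
#'
#' A record is `exceeding` iff at least one indicator value strictly exceeds
#' its limit (values exactly at the limit are compliant); violated
#' indicators are listed in threshold (schema) order.
#'
#' @param record named list with at least `values` (named numeric vector or
#'   list of indicator concentrations); or a single-row slice of a
#'   `contaminant_table`.
#' @param thresholds named numeric vector of limits covering every indicator
#'   present in the record.
#' @return The record with `status` (`"exceeding"`/`"compliant"`) and
#'   `violated_indicators` (character vector) filled in.
#' @export
classify_record <- function(record, thresholds) {
  vals <- unlist(record$values)
  if (is.null(vals)) stop("classify_record: record has no 'values'")
  missing_thr <- setdiff(names(vals), names(thresholds))
  if (length(missing_thr)) {
    stop("classify_record: no threshold for indicator '", missing_thr[1], "'")
  }
  schema <- intersect(names(thresholds), names(vals))
  violated <- schema[vals[schema] > thresholds[schema]]
  record$status <- if (length(violated)) "exceeding" else "compliant"
  record$violated_indicators <- violated
  record
}

#' Build detection records from a contaminant table
#'
#' @param table a `contaminant_table`.
#' @param predictions optional numeric vector of predicted risk values (one
#'   per row); attaches a `prediction` entry with the value and a coarse
#'   risk band (low < 0.3 <= medium < 0.6 <= high).
#' @return List of unclassified record lists.
#' @export
records_from_table <- function(table, predictions = NULL) {
  stopifnot(inherits(table, "contaminant_table"))
  ind <- attr(table, "indicators")
  X <- indicator_matrix(table)
  lapply(seq_len(nrow(table)), function(i) {
    rec <- list(
      sample_id = table$sample_id[i],
      batch_id = table$batch_id[i],
      region = table$region[i],
      detection_date = format(table$detection_date[i], "%Y-%m-%d"),
      values = as.list(setNames(unname(X[i, ]), ind$name))
    )
    if (!is.null(predictions)) {
      band <- if (predictions[i] < 0.3) "low" else if (predictions[i] < 0.6) "medium" else "high"
      rec$prediction <- list(risk_value = predictions[i], risk_band = band)
    }
    rec
  })
}

# ---- Merkle tree ------------------------------------------------------------

#' Merkle root of an ordered list of SHA-256 digests
#'
#' Pairwise SHA-256 of concatenated child digests; an odd node is paired
#' with itself. A single leaf is its own root; the empty list maps to the
#' SHA-256 of the empty string (documented sentinel).
#'
#' @param leaf_hashes character vector of 64-char hex digests.
#' @return 64-char hex digest.
#' @export
merkle_root <- function(leaf_hashes) {
  if (!length(leaf_hashes)) return(.sha256_hex(raw(0)))
  bad <- which(nchar(leaf_hashes) != 64 | grepl("[^0-9a-f]", tolower(leaf_hashes)))
  if (length(bad)) stop("merkle_root: malformed digest at position ", bad[1])
  level <- lapply(tolower(leaf_hashes), function(h) {
    as.raw(strtoi(substring(h, seq(1, 63, 2), seq(2, 64, 2)), 16L))
  })
  while (length(level) > 1) {
    if (length(level) %% 2 == 1) level <- c(level, level[length(level)])
    level <- lapply(seq(1, length(level), 2), function(i) {
      .sha256_raw(c(level[[i]], level[[i + 1]]))
    })
  }
  .raw2hex(level[[1]])
}

# ---- ledger state -----------------------------------------------------------

.genesis_prev <- strrep("0", 64)

#' Initialize a tiered ledger
#'
#' @param thresholds named numeric vector of per-indicator limits
#'   (default [default_thresholds()]).
#' @param keypair SM2 key pair for signing and local-store encryption;
#'   generated if omitted.
#' @param anchor_predictions `"exceeding_only"` (default: compliant records
#'   always go to the encrypted local store) or `"all"` (compliant records
#'   carrying a prediction are also anchored on-chain).
#' @return Object of class `ledger_state`.
#' @export
ledger_init <- function(thresholds = default_thresholds(), keypair = NULL,
                        anchor_predictions = c("exceeding_only", "all")) {
  anchor_predictions <- match.arg(anchor_predictions)
  if (is.null(keypair)) keypair <- sm2_keygen()
  structure(
    list(chain = list(), staged = list(), local_store = list(),
         thresholds = thresholds, keys = keypair,
         anchor_predictions = anchor_predictions),
    class = "ledger_state"
  )
}

#' @export
print.ledger_state <- function(x, ...) {
  nrec <- sum(vapply(x$chain, function(b) b$header$record_count, numeric(1)))
  cat("Tiered traceability ledger\n")
  cat(sprintf("  chain: %d block(s), %d on-chain record(s)\n", length(x$chain), nrec))
  cat(sprintf("  staged: %d   encrypted local store: %d\n",
              length(x$staged), length(x$local_store)))
  cat(sprintf("  anchoring policy: %s\n", x$anchor_predictions))
  invisible(x)
}

#' Route a classified record into the tiered store
#'
#' Exceeding records (and, under the `"all"` policy, compliant records with
#' predictions) are staged for the next block. Compliant records are
#' SM2-encrypted under the ledger public key and appended to the local
#' store.
#'
#' @param state a `ledger_state`.
#' @param record a detection record; classified on the fly if it has no
#'   `status` yet.
#' @return List with `state` (updated) and `routing`
#'   (`"chain"` or `"local"`).
#' @export
store_record <- function(state, record) {
  stopifnot(inherits(state, "ledger_state"))
  if (is.null(record$status)) record <- classify_record(record, state$thresholds)
  to_chain <- record$status == "exceeding" ||
    (state$anchor_predictions == "all" && !is.null(record$prediction))
  if (to_chain) {
    state$staged[[length(state$staged) + 1L]] <- record
    return(list(state = state, routing = "chain"))
  }
  ct <- sm2_encrypt(charToRaw(canonical_json(record)), state$keys)
  state$local_store[[length(state$local_store) + 1L]] <-
    list(sample_id = record$sample_id, ciphertext = ct)
  list(state = state, routing = "local")
}

.record_payload <- function(record) {
  record$signature <- NULL
  canonical_json(record)
}

#' Seal staged records into a new block
#'
#' Each record is signed (SM2, over its canonical serialization); the block
#' header stores the previous block hash (64 zeros for the genesis block), a
#' UTC timestamp, the Merkle root of the signed-record hashes and the record
#' count. The block hash is the SHA-256 of the canonically serialized
#' header.
#'
#' @param state a `ledger_state`.
#' @param records list of records to anchor; defaults to (and clears) the
#'   staged set. Every record must be exceeding or carry a prediction.
#' @return Updated `ledger_state`, chain one block longer.
#' @export
append_block <- function(state, records = NULL) {
  stopifnot(inherits(state, "ledger_state"))
  from_stage <- is.null(records)
  if (from_stage) records <- state$staged
  if (!length(records)) stop("append_block: no records to anchor")
  for (rec in records) {
    if (is.null(rec$status)) stop("append_block: unclassified record ", rec$sample_id)
    if (rec$status != "exceeding" && is.null(rec$prediction)) {
      stop("append_block: compliant record without prediction cannot be anchored (",
           rec$sample_id, ")")
    }
  }
  signed <- lapply(records, function(rec) {
    payload <- .record_payload(rec)
    rec$signature <- sm2_sign(charToRaw(payload), state$keys)
    rec
  })
  leaf <- vapply(signed, function(rec) .sha256_hex(charToRaw(canonical_json(rec))),
                 character(1))
  idx <- length(state$chain)
  prev <- if (idx == 0) .genesis_prev else state$chain[[idx]]$block_hash
  header <- list(index = idx, previous_hash = prev,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
                 merkle_root = merkle_root(leaf),
                 record_count = length(signed))
  block <- list(header = header, body = signed,
                block_hash = .sha256_hex(charToRaw(canonical_json(header))))
  state$chain[[idx + 1L]] <- block
  if (from_stage) state$staged <- list()
  state
}

#' Validate the hash chain
#'
#' Checks index continuity, previous-hash linkage, Merkle roots, header
#' hashes and every record signature.
#'
#' @param state a `ledger_state`.
#' @return List with `valid` (logical) and `first_invalid` (index of the
#'   first failing block, or `NA`).
#' @export
validate_chain <- function(state) {
  stopifnot(inherits(state, "ledger_state"))
  prev <- .genesis_prev
  for (i in seq_along(state$chain)) {
    block <- state$chain[[i]]
    h <- block$header
    fail <- function() list(valid = FALSE, first_invalid = i - 1L)
    if (is.null(h$index) || h$index != i - 1L) return(fail())
    if (!identical(h$previous_hash, prev)) return(fail())
    leaf <- vapply(block$body,
                   function(rec) .sha256_hex(charToRaw(canonical_json(rec))),
                   character(1))
    if (!identical(merkle_root(leaf), h$merkle_root)) return(fail())
    if (!identical(.sha256_hex(charToRaw(canonical_json(h))), block$block_hash)) {
      return(fail())
    }
    for (rec in block$body) {
      if (is.null(rec$signature) ||
          !sm2_verify(charToRaw(.record_payload(rec)), rec$signature, state$keys)) {
        return(fail())
      }
    }
    prev <- block$block_hash
  }
  list(valid = TRUE, first_invalid = NA_integer_)
}

#' Query on-chain records
#'
#' Three selectors over the anchored records: by sample ID, by batch, or by
#' detection-date range (closed-open, `[start, end)`). Each hit is tagged
#' with its block index and block timestamp.
#'
#' @param state a `ledger_state` with a valid chain.
#' @param by one of `"id"`, `"batch"`, `"time"`.
#' @param value sample ID (`by = "id"`) or batch ID (`by = "batch"`).
#' @param start,end dates for `by = "time"`; `start` must precede `end`.
#' @return List of matching records, each with `block_index` and
#'   `block_timestamp` added.
#' @export
ledger_query <- function(state, by = c("id", "batch", "time"),
                         value = NULL, start = NULL, end = NULL) {
  stopifnot(inherits(state, "ledger_state"))
  by <- match.arg(by)
  if (by == "time") {
    start <- as.Date(start); end <- as.Date(end)
    if (is.na(start) || is.na(end)) stop("ledger_query: invalid date(s)")
    if (start >= end) stop("ledger_query: 'start' must be before 'end'")
  } else if (is.null(value)) {
    stop("ledger_query: 'value' required for ", by, " queries")
  }
  hits <- list()
  for (block in state$chain) {
    for (rec in block$body) {
      keep <- switch(by,
        id = identical(rec$sample_id, value),
        batch = identical(rec$batch_id, value),
        time = {
          d <- as.Date(rec$detection_date)
          d >= start && d < end
        })
      if (keep) {
        rec$block_index <- block$header$index
        rec$block_timestamp <- block$header$timestamp
        hits[[length(hits) + 1L]] <- rec
      }
    }
  }
  hits
}

#' Decrypt the local store
#'
#' @param state a `ledger_state` whose key pair holds the private key.
#' @return List of decrypted compliant records.
#' @export
decrypt_local_store <- function(state) {
  stopifnot(inherits(state, "ledger_state"))
  lapply(state$local_store, function(entry) {
    jsonlite::fromJSON(rawToChar(sm2_decrypt(entry$ciphertext, state$keys)),
                       simplifyVector = FALSE)
  })
}

# ---- persistence ------------------------------------------------------------

#' Persist / load a ledger as JSON Lines
#'
#' The chain is written one block per line; the local store and the keystore
#' go to sibling files (`<path>.local`, `<path>.keys`).
#'
#' @param state a `ledger_state`.
#' @param path base file path.
#' @return `path` invisibly (write); a `ledger_state` (read).
#' @export
write_ledger <- function(state, path) {
  stopifnot(inherits(state, "ledger_state"))
  con <- file(path, "w", encoding = "UTF-8")
  for (block in state$chain) writeLines(canonical_json(block), con)
  close(con)
  con <- file(paste0(path, ".local"), "w", encoding = "UTF-8")
  for (entry in state$local_store) writeLines(canonical_json(entry), con)
  close(con)
  keys <- c(unclass(state$keys),
            list(thresholds = as.list(state$thresholds),
                 anchor_predictions = state$anchor_predictions))
  writeLines(canonical_json(keys), paste0(path, ".keys"))
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  keys <- jsonlite::fromJSON(paste0(path, ".keys"), simplifyVector = FALSE)
  kp <- structure(list(private = keys$private, public_x = keys$public_x,
                       public_y = keys$public_y), class = "sm2_keypair")
  state <- ledger_init(thresholds = unlist(keys$thresholds), keypair = kp,
                       anchor_predictions = keys$anchor_predictions)
  lines <- readLines(path, encoding = "UTF-8")
  state$chain <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
  lines <- readLines(paste0(path, ".local"), encoding = "UTF-8")
  state$local_store <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
  state
}
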