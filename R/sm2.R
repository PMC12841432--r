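# SM2 public-key cryptography (GB/T 32918 curve) implemented on OpenSSL
# big-number arithmetic: Jacobian-coordinate point arithmetic, fixed-base
# precomputation for the generator and for public keys. SHA-256 serves as
# the digest and KDF hash throughout (the curve and the signature/encryption
# protocols are SM2; the hash primitive is this package's documented
# choice). Signing and encryption derive their per-message nonces
# deterministically from the key and message so that ledger serializations
# are reproducible across processes.

.sm2 <- new.env(parent = emptyenv())

.hex2bn <- function(h) {
  h <- tolower(gsub("[^0-9a-fA-F]", "", h))
  if (nchar(h) %% 2 == 1) h <- paste0("0", h)
  openssl::bignum(as.raw(strtoi(substring(h, seq(1, nchar(h), 2),
                                          seq(2, nchar(h), 2)), 16L)))
}

.bn2hex <- function(b, width = 64) {
  r <- as.raw(b)
  h <- paste(sprintf("%02x", as.integer(r)), collapse = "")
  if (nchar(h) < width) h <- paste0(strrep("0", width - nchar(h)), h)
  h
}

.bn2raw32 <- function(b) {
  r <- as.raw(b)
  if (length(r) < 32) r <- c(as.raw(rep(0, 32 - length(r))), r)
  r
}

# runtime context: curve constants plus modular helpers bound to the
# openssl big-number routines (resolved once; avoids S3 dispatch in the
# point-arithmetic hot path)
.sm2_rt <- function() {
  if (!is.null(.sm2$rt)) return(.sm2$rt)
  ns <- asNamespace("openssl")
  MUL <- get("R_bignum_multiply", ns)
  MOD <- get("R_bignum_mod", ns)
  ADD <- get("R_bignum_add", ns)
  SUB <- get("R_bignum_subtract", ns)
  CMP <- get("R_bignum_compare", ns)
  INV <- get("R_bignum_mod_inv", ns)

  p <- .hex2bn("FFFFFFFEFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFF00000000FFFFFFFFFFFFFFFF")
  a <- .hex2bn("FFFFFFFEFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFF00000000FFFFFFFFFFFFFFFC")
  b <- .hex2bn("28E9FA9E9D9F5E344D5A9E4BCF6509A7F39789F515AB8F92DDBCBD414D940E93")
  n <- .hex2bn("FFFFFFFEFFFFFFFFFFFFFFFFFFFFFFFF7203DF6B21C6052B53BBF40939D54123")
  gx <- .hex2bn("32C4AE2C1F1981195F9904466A39C9948FE30BBFF2660BE1715A4589334C74C7")
  gy <- .hex2bn("BC3736A2F4F6779C59BDCEE36B692153D0A9877CC62A474002DF32E52139F0A0")
  zero <- openssl::bignum(0)

  rt <- list(
    p = p, a = a, b = b, n = n, gx = gx, gy = gy, zero = zero,
    one = openssl::bignum(1), two = openssl::bignum(2),
    three = openssl::bignum(3), four = openssl::bignum(4),
    eight = openssl::bignum(8),
    # inputs reduced mod p
    mul  = function(x, y) .Call(MOD, .Call(MUL, x, y), p),
    sqr  = function(x) .Call(MOD, .Call(MUL, x, x), p),
    add  = function(x, y) .Call(MOD, .Call(ADD, x, y), p),
    sub  = function(x, y) .Call(MOD, .Call(SUB, .Call(ADD, x, p), y), p),
    inv  = function(x) .Call(INV, x, p),
    # mod n variants for signature scalar algebra
    nmul = function(x, y) .Call(MOD, .Call(MUL, x, y), n),
    nadd = function(x, y) .Call(MOD, .Call(ADD, x, y), n),
    nsub = function(x, y) .Call(MOD, .Call(SUB, .Call(ADD, x, n), y), n),
    ninv = function(x) .Call(INV, x, n),
    nmod = function(x) .Call(MOD, x, n),
    iszero = function(x) .Call(CMP, x, zero) == 0L,
    lt   = function(x, y) .Call(CMP, x, y) < 0L,
    eq   = function(x, y) .Call(CMP, x, y) == 0L
  )
  .sm2$rt <- rt
  rt
}

# points: affine list(x=, y=) or NULL for the point at infinity;
# Jacobian list(X=, Y=, Z=) with Z == 0 meaning infinity.

.jac_inf <- function(rt) list(X = rt$one, Y = rt$one, Z = rt$zero)

.to_jac <- function(P, rt) {
  if (is.null(P)) return(.jac_inf(rt))
  list(X = P$x, Y = P$y, Z = rt$one)
}

.to_affine <- function(J, rt) {
  if (rt$iszero(J$Z)) return(NULL)
  zi <- rt$inv(J$Z)
  zi2 <- rt$sqr(zi)
  list(x = rt$mul(J$X, zi2), y = rt$mul(rt$mul(J$Y, zi2), zi))
}

# doubling, specialised for a = p - 3
.jac_double <- function(J, rt) {
  if (rt$iszero(J$Z) || rt$iszero(J$Y)) return(.jac_inf(rt))
  Z2 <- rt$sqr(J$Z)
  Y2 <- rt$sqr(J$Y)
  S <- rt$mul(rt$four, rt$mul(J$X, Y2))
  M <- rt$mul(rt$three, rt$mul(rt$sub(J$X, Z2), rt$add(J$X, Z2)))
  X3 <- rt$sub(rt$sqr(M), rt$add(S, S))
  Y3 <- rt$sub(rt$mul(M, rt$sub(S, X3)), rt$mul(rt$eight, rt$sqr(Y2)))
  Z3 <- rt$mul(rt$two, rt$mul(J$Y, J$Z))
  list(X = X3, Y = Y3, Z = Z3)
}

# mixed addition: Jacobian J + affine Q
.jac_add_affine <- function(J, Q, rt) {
  if (is.null(Q)) return(J)
  if (rt$iszero(J$Z)) return(.to_jac(Q, rt))
  Z1Z1 <- rt$sqr(J$Z)
  U2 <- rt$mul(Q$x, Z1Z1)
  S2 <- rt$mul(rt$mul(Q$y, J$Z), Z1Z1)
  H <- rt$sub(U2, J$X)
  r <- rt$sub(S2, J$Y)
  if (rt$iszero(H)) {
    if (rt$iszero(r)) return(.jac_double(J, rt))
    return(.jac_inf(rt))
  }
  HH <- rt$sqr(H)
  HHH <- rt$mul(H, HH)
  V <- rt$mul(J$X, HH)
  X3 <- rt$sub(rt$sub(rt$sqr(r), HHH), rt$add(V, V))
  Y3 <- rt$sub(rt$mul(r, rt$sub(V, X3)), rt$mul(J$Y, HHH))
  Z3 <- rt$mul(J$Z, H)
  list(X = X3, Y = Y3, Z = Z3)
}

# big-endian bit vector of a scalar, leading zeros stripped
.scalar_bits <- function(k) {
  r <- as.integer(as.raw(k))
  if (!length(r)) return(integer(0))
  bits <- integer(length(r) * 8L)
  for (i in seq_along(r)) {
    bits[((i - 1) * 8 + 1):(i * 8)] <- bitwAnd(bitwShiftR(r[i], 7:0), 1L)
  }
  first <- which(bits == 1L)[1]
  if (is.na(first)) return(integer(0))
  bits[first:length(bits)]
}

# plain double-and-add for an arbitrary affine point
.point_mul <- function(k, P) {
  rt <- .sm2_rt()
  bits <- .scalar_bits(rt$nmod(k))
  if (!length(bits)) return(NULL)
  J <- .jac_inf(rt)
  for (b in bits) {
    J <- .jac_double(J, rt)
    if (b == 1L) J <- .jac_add_affine(J, P, rt)
  }
  .to_affine(J, rt)
}

# 4-bit fixed-base comb table: tab[[i]][[v]] = v * 16^(i-1) * P (affine),
# i = 1..64, v = 1..15
.fixed_table <- function(P) {
  rt <- .sm2_rt()
  key <- paste0(.bn2hex(P$x), .bn2hex(P$y))
  tab <- .sm2$tables[[key]]
  if (!is.null(tab)) return(tab)
  tab <- vector("list", 64)
  base <- P
  for (i in 1:64) {
    row <- vector("list", 15)
    row[[1]] <- base
    J <- .to_jac(base, rt)
    for (v in 2:15) {
      J <- .jac_add_affine(J, base, rt)
      row[[v]] <- .to_affine(J, rt)
    }
    tab[[i]] <- row
    if (i < 64) {
      J <- .to_jac(base, rt)
      for (dd in 1:4) J <- .jac_double(J, rt)
      base <- .to_affine(J, rt)
    }
  }
  if (is.null(.sm2$tables)) .sm2$tables <- list()
  .sm2$tables[[key]] <- tab
  tab
}

# fixed-base multiplication: sum over 4-bit nibbles of k using the comb table
.point_mul_fixed <- function(k, P) {
  rt <- .sm2_rt()
  k <- rt$nmod(k)
  r <- as.integer(.bn2raw32(k))          # 32 bytes, big endian
  tab <- .fixed_table(P)
  J <- .jac_inf(rt)
  for (byte_i in seq_len(32)) {          # byte 1 is most significant
    byte <- r[33 - byte_i]               # least significant first
    lo <- bitwAnd(byte, 15L)
    hi <- bitwShiftR(byte, 4L)
    i_lo <- (byte_i - 1L) * 2L + 1L      # nibble index (16^(i-1))
    if (lo > 0L) J <- .jac_add_affine(J, tab[[i_lo]][[lo]], rt)
    if (hi > 0L) J <- .jac_add_affine(J, tab[[i_lo + 1L]][[hi]], rt)
  }
  .to_affine(J, rt)
}

.sm2_generator <- function() {
  rt <- .sm2_rt()
  list(x = rt$gx, y = rt$gy)
}

.sha256_raw <- function(x) as.raw(openssl::sha256(x))

.raw2hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

.sha256_hex <- function(x) .raw2hex(.sha256_raw(x))

# deterministic nonce: hash of (tag, secret, message, counter), reduced mod n
.det_nonce <- function(tag, secret_raw, msg_raw, counter) {
  rt <- .sm2_rt()
  h <- .sha256_raw(c(charToRaw(tag), secret_raw, msg_raw,
                     as.raw(c(counter %/% 256, counter %% 256))))
  rt$nmod(openssl::bignum(h))
}

#' Is a point on the SM2 curve?
#'
#' @param x_hex,y_hex coordinates as 64-character hex strings.
#' @return Logical: does `y^2 = x^3 + ax + b (mod p)` hold?
#' @export
sm2_on_curve <- function(x_hex, y_hex) {
  rt <- .sm2_rt()
  x <- .hex2bn(x_hex); y <- .hex2bn(y_hex)
  lhs <- rt$sqr(y)
  rhs <- rt$add(rt$add(rt$mul(rt$sqr(x), x), rt$mul(rt$a, x)), rt$b)
  rt$eq(lhs, rhs)
}

#' Generate an SM2 key pair
#'
#' The private scalar `d` is drawn from the session RNG (so `set.seed()`
#' makes key generation reproducible); the public key is `P = d * G`.
#'
#' @return Object of class `sm2_keypair`: list with hex-encoded `private`,
#'   `public_x`, `public_y`.
#' @export
#' @examples
#' set.seed(1)
#' kp <- sm2_keygen()
#' sm2_on_curve(kp$public_x, kp$public_y)
sm2_keygen <- function() {
  rt <- .sm2_rt()
  repeat {
    rb <- as.raw(sample.int(256L, 32L, replace = TRUE) - 1L)
    d <- openssl::bignum(rb) %% (rt$n - rt$two) + rt$one   # d in [1, n-2]
    if (!rt$iszero(d)) break
  }
  P <- .point_mul_fixed(d, .sm2_generator())
  structure(list(private = .bn2hex(d), public_x = .bn2hex(P$x),
                 public_y = .bn2hex(P$y)),
            class = "sm2_keypair")
}

#' @export
print.sm2_keypair <- function(x, ...) {
  cat("SM2 key pair\n")
  cat("  public x:", x$public_x, "\n")
  cat("  public y:", x$public_y, "\n")
  cat("  private : <", nchar(x$private) * 4, "bits hidden >\n")
  invisible(x)
}

#' Sign a message with SM2
#'
#' Produces the `(r, s)` signature of the SM2 digital signature scheme over
#' the SHA-256 digest of the message. The nonce is derived deterministically
#' from the private key and message, so signatures are reproducible.
#'
#' @param message raw vector or character scalar.
#' @param keypair an [sm2_keygen()] key pair.
#' @return List with hex strings `r` and `s`.
#' @export
sm2_sign <- function(message, keypair) {
  if (is.character(message)) message <- charToRaw(message)
  rt <- .sm2_rt()
  d <- .hex2bn(keypair$private)
  e <- rt$nmod(openssl::bignum(.sha256_raw(message)))
  drw <- .bn2raw32(d)
  for (counter in 1:64) {
    k <- .det_nonce("sm2-sign", drw, message, counter)
    if (rt$iszero(k)) next
    P1 <- .point_mul_fixed(k, .sm2_generator())
    r <- rt$nadd(e, P1$x)
    if (rt$iszero(r) || rt$iszero(rt$nadd(r, k))) next
    s <- rt$nmul(rt$ninv(rt$nadd(rt$one, d)), rt$nsub(k, rt$nmul(r, d)))
    if (rt$iszero(s)) next
    return(list(r = .bn2hex(r), s = .bn2hex(s)))
  }
  stop("sm2_sign: failed to derive a valid nonce")  # practically unreachable
}

#' Verify an SM2 signature
#'
#' @param message raw vector or character scalar.
#' @param signature list with hex `r`, `s` (from [sm2_sign()]).
#' @param public list or keypair with `public_x`, `public_y`.
#' @return Logical.
#' @export
sm2_verify <- function(message, signature, public) {
  if (is.character(message)) message <- charToRaw(message)
  rt <- .sm2_rt()
  ok <- tryCatch({
    r <- .hex2bn(signature$r); s <- .hex2bn(signature$s)
    if (rt$iszero(r) || rt$iszero(s) || !rt$lt(r, rt$n) || !rt$lt(s, rt$n)) {
      FALSE
    } else {
      t <- rt$nadd(r, s)
      if (rt$iszero(t)) {
        FALSE
      } else {
        P <- list(x = .hex2bn(public$public_x), y = .hex2bn(public$public_y))
        A <- .point_mul_fixed(s, .sm2_generator())
        B <- .point_mul_fixed(t, P)
        C <- if (is.null(A)) B else .to_affine(.jac_add_affine(.to_jac(A, rt), B, rt), rt)
        if (is.null(C)) {
          FALSE
        } else {
          e <- rt$nmod(openssl::bignum(.sha256_raw(message)))
          rt$eq(rt$nadd(e, C$x), r)
        }
      }
    }
  }, error = function(e) FALSE)
  isTRUE(ok)
}

# counter-mode KDF over SHA-256
.sm2_kdf <- function(z_raw, klen) {
  out <- vector("list", ceiling(klen / 32))
  for (ct in seq_along(out)) {
    out[[ct]] <- .sha256_raw(c(z_raw, as.raw(c(0, 0, ct %/% 256, ct %% 256))))
  }
  unlist(out)[seq_len(klen)]
}

.xor_raw <- function(a, b) as.raw(bitwXor(as.integer(a), as.integer(b)))

#' SM2 public-key encryption
#'
#' Classic SM2 hybrid encryption: an ephemeral scalar `k` gives
#' `C1 = k*G`; the shared point `k*P` is fed to a counter-mode KDF whose
#' keystream masks the plaintext (`C2`), with an integrity digest `C3`.
#' Output layout is `C1 || C3 || C2`, hex encoded. The ephemeral scalar is
#' derived deterministically from the public key and plaintext.
#'
#' @param message raw vector or character scalar.
#' @param public key pair or list with `public_x`, `public_y`.
#' @return Hex-string ciphertext.
#' @export
sm2_encrypt <- function(message, public) {
  if (is.character(message)) message <- charToRaw(message)
  if (!length(message)) stop("sm2_encrypt: empty message")
  rt <- .sm2_rt()
  P <- list(x = .hex2bn(public$public_x), y = .hex2bn(public$public_y))
  seed_raw <- c(.bn2raw32(P$x), .bn2raw32(P$y))
  for (counter in 1:64) {
    k <- .det_nonce("sm2-enc", seed_raw, message, counter)
    if (rt$iszero(k)) next
    C1 <- .point_mul_fixed(k, .sm2_generator())
    S <- .point_mul_fixed(k, P)
    z <- c(.bn2raw32(S$x), .bn2raw32(S$y))
    t <- .sm2_kdf(z, length(message))
    if (all(t == as.raw(0))) next
    C2 <- .xor_raw(message, t)
    C3 <- .sha256_raw(c(.bn2raw32(S$x), message, .bn2raw32(S$y)))
    return(paste0("04", .bn2hex(C1$x), .bn2hex(C1$y),
                  .raw2hex(C3), .raw2hex(C2)))
  }
  stop("sm2_encrypt: failed to derive a usable ephemeral key")
}

#' SM2 decryption
#'
#' @param ciphertext hex string from [sm2_encrypt()].
#' @param keypair key pair holding the private scalar.
#' @return Raw plaintext vector; errors if the integrity digest fails.
#' @export
sm2_decrypt <- function(ciphertext, keypair) {
  h <- tolower(ciphertext)
  if (nchar(h) < 2 + 128 + 64 + 2 || substr(h, 1, 2) != "04") {
    stop("sm2_decrypt: malformed ciphertext")
  }
  x1 <- substr(h, 3, 66); y1 <- substr(h, 67, 130)
  C3 <- substr(h, 131, 194)
  C2 <- substr(h, 195, nchar(h))
  if (!sm2_on_curve(x1, y1)) stop("sm2_decrypt: C1 not on curve")
  d <- .hex2bn(keypair$private)
  C1 <- list(x = .hex2bn(x1), y = .hex2bn(y1))
  S <- .point_mul(d, C1)
  if (is.null(S)) stop("sm2_decrypt: degenerate shared point")
  z <- c(.bn2raw32(S$x), .bn2raw32(S$y))
  nb <- nchar(C2) / 2
  t <- .sm2_kdf(z, nb)
  c2raw <- as.raw(strtoi(substring(C2, seq(1, nchar(C2), 2),
                                   seq(2, nchar(C2), 2)), 16L))
  msg <- .xor_raw(c2raw, t)
  C3chk <- .raw2hex(.sha256_raw(c(.bn2raw32(S$x), msg, .bn2raw32(S$y))))
  if (!identical(C3chk, C3)) stop("sm2_decrypt: integrity check failed")
  msg
}
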