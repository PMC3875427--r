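# Internal helpers: deterministic ordering, seed derivation, set keys.

# Deterministic 31-bit substream seed from a base seed and integer tags.
# Mixing constant 69069 (Marsaglia) keeps products exactly representable
# in doubles: (2^31) * 69069 < 2^53.
derive_seed <- function(base, ...) {
  s <- as.double(base %% 2147483647)
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) %% 2147483647) %% 2147483647
  }
  as.integer(s)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards (substreams are order-independent).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

set_key <- function(x) paste(x, collapse = ",")

# Global tie-break used by every sort over biclusters: p ascending
# (NA last), then lexicographically smallest gene id, then the full
# collapsed gene list for total determinism.
bic_tiebreak_frame <- function(b) {
  first_gene <- vapply(b$genes, function(g) if (length(g)) min(g) else "", "")
  full <- vapply(b$genes, set_key, "")
  list(p = b$p_value, first_gene = first_gene, full = full)
}

order_biclusters <- function(b, primary = c("size", "p_value")) {
  primary <- match.arg(primary)
  tb <- bic_tiebreak_frame(b)
  if (primary == "size") {
    order(-b$size, tb$p, tb$first_gene, tb$full, na.last = TRUE)
  } else {
    order(tb$p, -b$size, tb$first_gene, tb$full, na.last = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
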