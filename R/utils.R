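# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit sub-seed derived from a master seed and a string tag,
# so adding molecules to a collection never reshuffles the seeds of others.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (31L^(seq_along(utf8ToInt(tag)) %% 8L)))
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

stop_ws <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "whalescreen_error")))
}

# Formal charge implied by a SMILES string: sum of bracket-atom charges.
# Used only to validate that Gasteiger partial charges conserve total charge.
smiles_formal_charge <- function(smiles) {
  vapply(smiles, function(s) {
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (!length(brackets)) return(0L)
    q <- vapply(brackets, function(b) {
      sign_tok <- regmatches(b, gregexpr("[+-][0-9]*", b))[[1]]
      # drop charge-like tokens inside isotope/atom-class positions: SMILES
      # puts charge at the end of the bracket, after the element symbol
      if (!length(sign_tok)) return(0L)
      sum(vapply(sign_tok, function(tk) {
        sgn <- if (substr(tk, 1, 1) == "+") 1L else -1L
        num <- substr(tk, 2, nchar(tk))
        if (nzchar(num)) sgn * as.integer(num) else sgn
      }, integer(1)))
    }, integer(1))
    sum(q)
  }, integer(1), USE.NAMES = FALSE)
}
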