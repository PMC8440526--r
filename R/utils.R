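# Internal validation helpers shared across modules.

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "osmofret_invalid_parameter")
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x),
          class = "osmofret_invalid_parameter")
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower),
          class = "osmofret_invalid_parameter")
  }
  invisible(as.integer(x))
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "osmofret_invalid_parameter")
  }
  invisible(data)
}

# One RNG sandbox per generator call: evaluates `expr` under a local seed
# without touching the caller's .Random.seed.
with_local_seed <- function(seed, expr) {
  assert_count(seed, "seed")
  withr::with_seed(as.integer(seed), expr)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

assert_protein_sequence <- function(seq, name = "sequence", min_length = 2L) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single string.", name),
          class = "osmofret_invalid_parameter")
  }
  residues <- strsplit(toupper(seq), "")[[1]]
  if (length(residues) < min_length) {
    abort(sprintf("`%s` must contain at least %d residues.", name, min_length),
          class = "osmofret_invalid_parameter")
  }
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf("`%s` contains non-standard residue(s): %s.",
                  name, paste(bad, collapse = ", ")),
          class = "osmofret_alphabet_error")
  }
  residues
}
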