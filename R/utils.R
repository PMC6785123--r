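# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which would
# turn 4/22 = 18.18... -> 18 either way but 0.5 -> 0; table proportions and
# integer percentages in reports use this rule).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# RNG kinds are pinned so identical seeds give identical output across
# sessions regardless of the session's RNGkind.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Trimmed, non-empty character check used by readers.
chr_trim <- function(x) {
  gsub("^[ \t]+|[ \t]+$", "", as.character(x))
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
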