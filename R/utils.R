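# internal helpers

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "d0.5cc" -> "d0_5cc" etc.; used for cohort-table column names
safe_name <- function(x) gsub(".", "_", x, fixed = TRUE)

# pretty volume label: 0.5 -> "0.5", 1 -> "1"
vol_label <- function(x) sub("\\.0$", "", sprintf("%.1f", x))
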