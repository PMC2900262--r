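# internal helpers shared across modules

# 96-well coordinates in row-major order: A1..A12, B1..B12, ...
plate_wells <- function(n, offset = 0) {
  if (n + offset > 96) {
    stop("plate capacity exceeded: ", n + offset, " wells requested (max 96)")
  }
  all <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  all[seq_len(n) + offset]
}

is_valid_well <- function(well) {
  grepl("^[A-H](1[0-2]|[1-9])$", well)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
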