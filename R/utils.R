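# structured conditions so the CLI can map failures to exit codes
.fail_validation <- function(msg) {
  stop(errorCondition(msg, class = c("ctpdeconv_validation_error", "error")))
}

.fail_solver <- function(msg) {
  stop(errorCondition(msg, class = c("ctpdeconv_solver_failure", "error")))
}

# coerce tissue-curve input to voxels x T matrix, remembering spatial dims
.as_voxel_matrix <- function(C, T_) {
  if (is.null(dim(C))) {
    if (length(C) %% T_ != 0) .fail_validation("curve length incompatible with system size")
    return(list(m = matrix(C, ncol = T_), sdim = c(length(C) / T_, 1L, 1L)))
  }
  d <- dim(C)
  if (d[length(d)] != T_)
    .fail_validation(sprintf("time axis mismatch: data has %d frames, system has %d",
                             d[length(d)], T_))
  sdim <- c(d[-length(d)], 1L, 1L)[1:3]
  list(m = matrix(C, ncol = T_), sdim = sdim)
}

# run a block with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# golden-ratio equidistributed sequence on (-1, 1), deterministic
.golden_jitter <- function(n) {
  if (n == 0L) return(numeric(0))
  2 * (((seq_len(n) * 0.6180339887498949) %% 1) - 0.5)
}
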