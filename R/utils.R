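`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a given seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream" (still advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

empty_exclusion_log <- function() {
  data.frame(snp_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

add_exclusions <- function(log, snp_id, reason) {
  if (length(snp_id) == 0L) return(log)
  rbind(log, data.frame(snp_id = snp_id, reason = reason,
                        stringsAsFactors = FALSE))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0
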