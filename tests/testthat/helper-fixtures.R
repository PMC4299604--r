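# shared fixture helpers: built in code, no stored data

log_spaced <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# all permutations of a small integer vector (used for scar-order invariance)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# a random 20-nt guide within the GC bounds, from the current RNG stream
random_guide <- function() {
  repeat {
    g <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    if (guide_gc_ok(g)) return(g)
  }
}

# step schedule for a single-input netlist: un-induced history, ON at t = 0
induction_at_zero <- function(on_level = 1040, input = "pIn") {
  s <- data.frame(time = c(-1e9, 0), lv = c(0, on_level))
  names(s)[2] <- input
  s
}
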