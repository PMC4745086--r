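# internal helpers shared across modules

# round half away from zero (base round() is banker's)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L || all(x == -Inf)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

stop_validation <- function(msg) {
  rlang::abort(msg, class = "unitome_validation_error")
}

stop_parse <- function(msg) {
  rlang::abort(msg, class = "unitome_parse_error")
}

# canonical unordered string pair: a <= b elementwise
canonical_pair <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

# strip a Pfam version suffix ("PF13465.1" -> "PF13465")
strip_pfam_version <- function(acc) {
  sub("\\.\\d+$", "", acc)
}
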