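# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-up decimal rounding for reported percentages (base round() is
# round-half-even, which disagrees with how the summary statistics are printed)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_ <- function(...) stop(..., call. = FALSE)

# provenance line written at the top of every result TSV
provenance_line <- function(seed = NA) {
  ver <- tryCatch(as.character(utils::packageVersion("phyllopan")),
                  error = function(e) "dev")
  sprintf("# phyllopan %s; seed=%s; written=%s", ver, as.character(seed),
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}
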