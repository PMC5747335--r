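trim_ws <- function(x) {
  if (is.null(x) || length(x) == 0L) return("")
  x <- as.character(x)[1]
  if (is.na(x)) return("")
  gsub("^[ \t\r\n]+|[ \t\r\n]+$", "", x)
}

is_blank <- function(x) !nzchar(trim_ws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# scalar accessor tolerant of NULL / empty
chr1 <- function(x, default = "") {
  if (is.null(x) || length(x) == 0L) return(default)
  v <- as.character(x)[1]
  if (is.na(v)) default else v
}
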