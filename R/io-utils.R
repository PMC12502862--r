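# Exact-precision CSV I/O. fwrite's default numeric formatting keeps 15
# significant digits, which is not enough for bitwise round trips; doubles
# are therefore rendered as %.17g strings (guaranteed to parse back to the
# identical double) before writing.

.writeExactCSV <- function(df, file) {
  df <- data.table::as.data.table(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]]))
      data.table::set(df, j = nm, value = sprintf("%.17g", df[[nm]]))
  }
  data.table::fwrite(df, file)
  invisible(file)
}

.readNumericCSV <- function(file) {
  data.table::fread(file, colClasses = "numeric")
}
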