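# Builders for small text fixtures, generated in code at test time.

# A classic DSSP fixture: fixed-column data lines under the '  #  RESIDUE'
# header. `rows` is a data.frame with columns chain, aa, ss ('!' in aa
# marks a discontinuity row).
dssp_fixture <- function(rows) {
  hdr <- c("==== Secondary Structure Definition; fixture ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  body <- vapply(seq_len(nrow(rows)), function(i) {
    aa <- rows$aa[i]
    # cols: 12 = chain, 14 = aa, 17 = summary SSE code
    if (aa == "!")
      return(sprintf("%5d %4d %s %s", i, i, " ", "!"))
    sprintf("%5d %4d %s %s  %s", i, i, rows$chain[i], aa, rows$ss[i])
  }, "")
  c(hdr, body)
}

write_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

tiny_records <- function() {
  list(
    a = protein_record("a", "ACDEFGHIKLMN", "HHHCHHHCHHHC"),
    b = protein_record("b", "ACDEFGHIKLMN", "HHHHHHHCHHHC"))
}
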