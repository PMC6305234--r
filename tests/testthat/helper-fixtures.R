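# In-code fixtures: write tiny dataset / alignment files into tempdir.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

write_dataset_files <- function(tab, seqs, ss = NULL) {
  table_path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(table = table_path,
       fasta = write_fasta(seqs),
       ss = if (!is.null(ss)) write_fasta(ss) else NULL)
}

# A small hand-designed labelled dataset touching all order classes.
toy_dataset <- function() {
  tab <- data.frame(
    id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    label = c("secretory", "secretory", "secretory",
              "non_secretory", "non_secretory", "non_secretory"),
    group = c("g1", "g1", "g2", "g1", "g2", "g2"),
    stringsAsFactors = FALSE)
  seqs <- c(
    P1 = "AAADEAAAKKKDEKKK",   # two DE motifs, contrasting charge
    P2 = "GGGDEGGGWTALAAAA",   # DE plus a downstream core LIR (W..L)
    P3 = "MKKDEAAAADDEAD",     # overlapping-ish motifs
    P4 = "AAADEAAAA",
    P5 = "IVLDEIVLAAA",        # hydrophobic context
    P6 = "DEDEAAAAAA")         # tandem DE at the N-terminus
  ss <- c(
    P1 = "CCCHHHHHCCCCCCCC",
    P2 = "HHHHHCCCCCCEEEEE",
    P3 = "CCCHECCCCCCCCC",
    P4 = "HHHHHHHHH",
    P5 = "CCCCHHHHEEE",
    P6 = "HCCCEEEEEE")
  stopifnot(all(nchar(seqs) == nchar(ss)))
  files <- write_dataset_files(tab, seqs, ss)
  read_dataset(files$table, files$fasta, files$ss)
}
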