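# Build an indexed BAM fixture from generated SAM text.
# `pairs` is a data.frame with columns qname, pos (1-based leftmost),
# len (fragment length), mapq1, mapq2, dup (logical).
makeBamFixture <- function(pairs, contig = "chrT", contigLen = 5000L,
                           readLen = 50L) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, contigLen))
  seqs <- strrep("A", readLen)
  qual <- strrep("I", readLen)
  cigar <- paste0(readLen, "M")
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    dupBit <- if (isTRUE(p$dup)) 1024L else 0L
    pos2 <- p$pos + p$len - readLen
    r1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
                  p$qname, 99L + dupBit, contig, p$pos, p$mapq1, cigar,
                  pos2, p$len, seqs, qual)
    r2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
                  p$qname, 147L + dupBit, contig, pos2, p$mapq2, cigar,
                  p$pos, -p$len, seqs, qual)
    data.frame(pos = c(p$pos, pos2), line = c(r1, r2))
  })
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$pos), ]
  sam <- tempfile(fileext = ".sam")
  writeLines(c(lines, recs$line), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
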