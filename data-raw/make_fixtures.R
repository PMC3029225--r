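# One-off generator for the packaged synthetic sequence fixtures.
# Deterministic; outputs are committed as plain text under inst/extdata/.

set.seed(20110104)

amp_start <- 618L; amp_end <- 2007L
n <- amp_end - amp_start + 1L
seq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
at <- function(pos) pos - amp_start + 1L

# documented bases at variant positions (ref alleles of the 41-variant catalogue)
ref_alleles <- c(
  `663` = "A", `681` = "T", `709` = "G", `723` = "A", `735` = "A",
  `747` = "A", `752` = "C", `789` = "T", `813` = "A", `827` = "A",
  `839` = "A", `929` = "A", `942` = "A", `951` = "G", `953` = "T",
  `961` = "T", `980` = "T", `990` = "T", `1005` = "T", `1009` = "C",
  `1027` = "A", `1041` = "A", `1048` = "C", `1095` = "T", `1107` = "T",
  `1119` = "T", `1187` = "T", `1282` = "G", `1310` = "C", `1382` = "A",
  `1391` = "T", `1393` = "G", `1413` = "T", `1442` = "G", `1462` = "G",
  `1494` = "C", `1503` = "G", `1541` = "T", `1555` = "A", `1598` = "G")
# curated stem partners (base needed at the partner position)
partners <- c(
  `700` = "T", `696` = "A", `692` = "C", `772` = "T", `858` = "T",
  `916` = "T", `938` = "C", `968` = "A", `999` = "A", `1080` = "A",
  `1330` = "G", `1368` = "T", `1436` = "T", `1422` = "G", `1516` = "T")
# C homopolymer 957-960 bounded by non-C, so an extra C left-normalises to 956insC
homopol <- c(`956` = "A", `957` = "C", `958` = "C", `959` = "C", `960` = "C")

for (v in list(ref_alleles, partners, homopol))
  seq[at(as.integer(names(v)))] <- unname(v)

stopifnot(seq[at(961)] == "T", seq[at(956)] != "C", seq[at(1494)] == "C",
          seq[at(1555)] == "A")

writeLines(c(
  ">rnr1_amplicon_synthetic rCRS-like synthetic amplicon, positions 618-2007 (1-based)",
  vapply(seq(1, n, 70), function(i) paste(seq[i:min(i + 69, n)], collapse = ""),
         character(1))),
  "inst/extdata/rnr1_reference_synthetic.fasta")

# --- GJB2 coding sequence (synthetic stand-in, correct length 678 nt) ---
set.seed(86849)
g <- sample(c("A", "C", "G", "T"), 678, replace = TRUE)
g[1:3] <- c("A", "T", "G")
g[676:678] <- c("T", "A", "A")
# documented bases at tested positions; contexts chosen so that the printed
# names 235delC and 299delAT are already left-normalised
g[234:236] <- c("A", "C", "G")
g[298:302] <- c("G", "A", "T", "C", "G")
writeLines(c(
  ">GJB2_CDS_synthetic synthetic stand-in coding sequence, cDNA coordinates 1-678",
  vapply(seq(1, 678, 70), function(i) paste(g[i:min(i + 69, 678)], collapse = ""),
         character(1))),
  "inst/extdata/gjb2_cds_synthetic.fasta")
cat("done\n")
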