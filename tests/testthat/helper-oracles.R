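# Independent brute-force oracles used to freeze expected values.

# Poisson-binomial pmf by explicit enumeration over all 2^n site subsets.
enum_poisson_binomial <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1L)
  if (n == 0L) return(1)
  for (mask in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    pmf[sum(bits) + 1L] <- pmf[sum(bits) + 1L] +
      prod(ifelse(bits == 1L, p, 1 - p))
  }
  pmf
}

# Natural isotope pattern by multinomial enumeration per element: for each
# element, enumerate every allocation of its atoms to isotopes, then combine
# element offset distributions by an explicit nested sum. Independent of the
# package's iterated polynomial convolution.
enum_natural_pattern <- function(counts, abund_table, length_out) {
  element_dist <- function(n, ab) {
    ab <- ab / sum(ab)
    k <- length(ab)
    dist <- numeric((k - 1L) * n + 1L)
    # compositions of n atoms over k isotopes
    rec <- function(pos, left, alloc) {
      if (pos == k) {
        alloc[k] <- left
        offset <- sum(alloc * (seq_len(k) - 1L))
        prob <- factorial(n) / prod(factorial(alloc)) * prod(ab^alloc)
        dist[offset + 1L] <<- dist[offset + 1L] + prob
        return(invisible())
      }
      for (a in 0:left) rec(pos + 1L, left - a, { alloc[pos] <- a; alloc })
    }
    rec(1L, n, integer(k))
    dist
  }
  total <- 1
  for (sym in names(counts)) {
    d <- element_dist(counts[[sym]], abund_table[[sym]])
    new <- numeric(min(length_out, length(total) + length(d) - 1L))
    for (i in seq_along(total)) {
      for (j in seq_along(d)) {
        if (i + j - 1L <= length(new)) {
          new[i + j - 1L] <- new[i + j - 1L] + total[i] * d[j]
        }
      }
    }
    total <- new
  }
  out <- numeric(length_out)
  out[seq_along(total)] <- total
  out
}

# abundances matching the package's pinned table, restated independently
ORACLE_ABUND <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  Cl = c(0.7576, 0, 0.2424)
)

# double-loop convolution oracle
brute_convolve <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (i + j - 1L <= len) out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
  }
  out
}

# minimal single-scan centroided mzML document (uncompressed 64-bit floats)
write_tiny_mzml <- function(mz, it, path) {
  enc64 <- function(x) jsonlite::base64_enc(writeBin(x, raw(), size = 8,
                                                     endian = "little"))
  arr <- function(x, acc, name) {
    b <- enc64(x)
    sprintf(paste0(
      "<binaryDataArray encodedLength=\"%d\">",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
      "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
      "<cvParam cvRef=\"MS\" accession=\"%s\" name=\"%s\" value=\"\"/>",
      "<binary>%s</binary></binaryDataArray>"), nchar(b), acc, name, b)
  }
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>\n",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">",
    "<cvList count=\"1\"><cv id=\"MS\" fullName=\"PSI-MS\" URI=\"http://x\"/></cvList>",
    "<fileDescription><fileContent>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000579\" name=\"MS1 spectrum\" value=\"\"/>",
    "</fileContent></fileDescription>",
    "<softwareList count=\"1\"><software id=\"s\" version=\"1\"/></softwareList>",
    "<instrumentConfigurationList count=\"1\"><instrumentConfiguration id=\"ic\"/>",
    "</instrumentConfigurationList>",
    "<dataProcessingList count=\"1\"><dataProcessing id=\"dp\">",
    "<processingMethod order=\"1\" softwareRef=\"s\"/></dataProcessing>",
    "</dataProcessingList>",
    "<run id=\"r\" defaultInstrumentConfigurationRef=\"ic\">",
    "<spectrumList count=\"1\" defaultDataProcessingRef=\"dp\">",
    sprintf("<spectrum index=\"0\" id=\"scan=1\" defaultArrayLength=\"%d\">",
            length(mz)),
    "<cvParam cvRef=\"MS\" accession=\"MS:1000127\" name=\"centroid spectrum\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000511\" name=\"ms level\" value=\"1\"/>",
    "<binaryDataArrayList count=\"2\">",
    arr(mz, "MS:1000514", "m/z array"),
    arr(it, "MS:1000515", "intensity array"),
    "</binaryDataArrayList></spectrum></spectrumList></run></mzML>")
  writeLines(doc, path)
  path
}
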