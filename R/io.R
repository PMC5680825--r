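#' Read a phased VCF into a haplotype panel
#'
#' Loads a VCF of biallelic SNPs with diploid GT fields and returns
#' the phased allele sequences plus the marker map. Phase follows the
#' `|` separator: the left allele goes to haplotype 1, the right to
#' haplotype 2. Unphased genotypes (`/` separator) are either
#' rejected (`require_phase = TRUE`) or loaded with both alleles
#' missing; fully missing genotypes (`./.`, `.|.`, `.`) are always
#' loaded as missing.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param require_phase Reject non-missing unphased genotypes?
#' @return A list with elements `panel` ([haplotype_panel()]) and
#'   `map` ([marker_map()]).
#' @export
read_phased_vcf <- function(path, require_phase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample name in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  nrec <- nrow(fix)
  if (nrec == 0L) stop("VCF contains no variant records")
  # line number of record i in the file, for error messages
  rec_line <- function(i) length(v@meta) + 1L + i
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic site at line ", rec_line(which(multi)[1]),
         " (", fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"],
         "); only biallelic SNPs are supported")
  ref <- fix[, "REF"]
  if (any(is.na(alt)) || any(nchar(ref) != 1L) || any(nchar(alt) != 1L)) {
    i <- which(is.na(alt) | nchar(ref) != 1L | nchar(alt) != 1L)[1]
    stop("non-SNP record at line ", rec_line(i), "; only biallelic SNPs are supported")
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[is.na(ids) | ids == ".", "CHROM"], "_",
                                         fix[is.na(ids) | ids == ".", "POS"])
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    a1 = ref, a2 = alt, stringsAsFactors = FALSE)

  gtf <- sub(":.*", "", gt[, -1, drop = FALSE])  # GT is the first FORMAT field
  dim(gtf) <- c(nrec, length(samples))           # sub() drops the dim attribute
  gtf[is.na(gtf)] <- "."                         # vcfR encodes missing GT as NA
  ok <- grepl("^(\\.|[01.]([|/])[01.])$", gtf)
  dim(ok) <- dim(gtf)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed genotype '", gtf[bad[1], bad[2]], "' for sample ",
         samples[bad[2]], " at line ", rec_line(bad[1]))
  }
  unphased <- grepl("/", gtf, fixed = TRUE)
  # unphased but fully-missing calls carry no phase information; never rejected
  unphased_informative <- unphased & !(gtf %in% "./.")
  dim(unphased_informative) <- dim(gtf)
  if (require_phase && any(unphased_informative)) {
    bad <- which(unphased_informative, arr.ind = TRUE)[1, ]
    stop("unphased genotype '", gtf[bad[1], bad[2]], "' for sample ",
         samples[bad[2]], " at line ", rec_line(bad[1]),
         " (require_phase = TRUE)")
  }
  a1 <- suppressWarnings(as.integer(substr(gtf, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gtf, 3, 3)))
  a1[unphased] <- NA_integer_
  a2[unphased] <- NA_integer_
  h1 <- matrix(a1, nrow = nrec)
  h2 <- matrix(a2, nrow = nrec)
  # markers sorted by position within chromosome (chromosomes keep
  # their order of first appearance)
  chrom_lev <- unique(map$chrom)
  o <- order(match(map$chrom, chrom_lev), map$pos)
  map <- map[o, , drop = FALSE]; rownames(map) <- NULL
  panel <- haplotype_panel(t(h1[o, , drop = FALSE]), t(h2[o, , drop = FALSE]),
                           map, ids = samples)
  list(panel = panel, map = panel$map)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotypes, using `|` as the
#' phase separator and `.` for missing alleles. The written file
#' round-trips through [read_phased_vcf()].
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  map <- panel$map
  a1 <- t(panel$hap1); a2 <- t(panel$hap2)  # markers x animals
  gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                      ifelse(is.na(a2), ".", a2)),
               nrow = nrow(map))
  header <- c("##fileformat=VCFv4.2",
              "##source=lethalscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$ids), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$marker, map$a1, map$a2,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

.norm_unknown <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", ".", "NA", "0")] <- "0"
  x
}

#' Read a pedigree table
#'
#' Tab-separated file with header columns `animal`, `sire`, `dam` and
#' optionally `line` and `sex`. Unknown parents may be coded as `0`,
#' `.`, `NA` or empty and are normalised to the token `"0"`. The
#' pedigree is checked for duplicate animals, cycles (no animal may
#' be its own ancestor) and sex consistency (a recorded sire must not
#' be female, a recorded dam must not be male).
#'
#' @param path Path to the pedigree file.
#' @return A `data.frame` with columns `animal`, `sire`, `dam`,
#'   `line`, `sex` (sex in `M`/`F`/`U`).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  need <- c("animal", "sire", "dam")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("pedigree file lacks mandatory column(s): ", paste(miss, collapse = ", "))
  ped <- data.frame(animal = as.character(d$animal),
                    sire = .norm_unknown(d$sire),
                    dam = .norm_unknown(d$dam),
                    line = if ("line" %in% names(d)) as.character(d$line) else "unknown",
                    sex = if ("sex" %in% names(d)) as.character(d$sex) else "U",
                    stringsAsFactors = FALSE)
  ped$sex <- toupper(substr(ped$sex, 1, 1))
  ped$sex[!ped$sex %in% c("M", "F")] <- "U"
  validate_pedigree(ped)
}

#' Validate a pedigree table
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam` and
#'   optionally `sex` (`M`/`F`/`U`).
#' @return The validated pedigree (invisibly classed as plain
#'   `data.frame`).
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$animal))
    stop("duplicate animal in pedigree: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  if (is.null(ped$sex)) ped$sex <- "U"
  sex <- ped$sex[match(ped$sire, ped$animal)]
  bad <- !is.na(sex) & sex == "F"
  if (any(bad))
    stop("animal recorded female is used as sire: ",
         paste(unique(ped$sire[bad]), collapse = ", "))
  sex <- ped$sex[match(ped$dam, ped$animal)]
  bad <- !is.na(sex) & sex == "M"
  if (any(bad))
    stop("animal recorded male is used as dam: ",
         paste(unique(ped$dam[bad]), collapse = ", "))
  cyc <- pedigree_cycle(ped)
  if (!is.null(cyc))
    stop("pedigree contains a cycle: ", paste(cyc, collapse = " -> "))
  ped
}

# Kahn topological sort over parent -> offspring edges; returns one
# cycle (as a character vector) if the pedigree is not acyclic.
pedigree_cycle <- function(ped) {
  ids <- ped$animal
  n <- length(ids)
  pi1 <- match(ped$sire, ids)
  pi2 <- match(ped$dam, ids)
  indeg <- (!is.na(pi1)) + (!is.na(pi2))
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(pi1[k], pi2[k])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], k)
    }
  }
  queue <- which(indeg == 0L)
  done <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    done <- done + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (done == n) return(NULL)
  # walk parent pointers inside the residual set until a repeat
  residual <- which(indeg > 0L)
  v <- residual[[1]]
  seen <- integer(0)
  while (!v %in% seen) {
    seen <- c(seen, v)
    p <- c(pi1[v], pi2[v])
    p <- p[!is.na(p) & p %in% residual]
    v <- p[[1]]
  }
  cycle <- seen[which(seen == v):length(seen)]
  c(ids[cycle], ids[v])
}

#' Write a pedigree table
#' @param ped Pedigree data frame (`animal`, `sire`, `dam`, `line`, `sex`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, intersect(c("animal", "sire", "dam", "line", "sex"),
                                     names(ped))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read litter phenotype records
#'
#' Tab-separated file with header columns `sow`, `boar`, `tnb`,
#' `nba`, `nsb`, `mum` and optionally `litter`. Counts must be
#' non-negative and satisfy `nba + nsb <= tnb`; the number of
#' mummified piglets is recorded independently of TNB because farm
#' conventions differ on whether mummies are included in total born.
#' Rows violating the count constraints are dropped with a message;
#' the dropped count is attached as attribute `"dropped"`.
#'
#' @param path Path to the litter file.
#' @return A `data.frame` with columns `litter`, `sow`, `boar`,
#'   `tnb`, `nba`, `nsb`, `mum`.
#' @export
read_litters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  names(d) <- tolower(names(d))
  need <- c("sow", "boar", "tnb", "nba", "nsb", "mum")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("litter file lacks mandatory column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(litter = if ("litter" %in% names(d)) as.character(d$litter)
                             else as.character(seq_len(nrow(d))),
                    sow = as.character(d$sow), boar = as.character(d$boar),
                    tnb = as.integer(d$tnb), nba = as.integer(d$nba),
                    nsb = as.integer(d$nsb), mum = as.integer(d$mum),
                    stringsAsFactors = FALSE)
  cnt <- as.matrix(out[, c("tnb", "nba", "nsb", "mum")])
  bad <- apply(is.na(cnt) | cnt < 0L, 1, any) | (out$nba + out$nsb > out$tnb)
  if (any(bad)) {
    message(sum(bad), " litter record(s) dropped (negative/missing counts or nba + nsb > tnb)")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- sum(bad)
  out
}

#' Write litter records
#' @param litters Litter data frame as returned by [read_litters()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_litters <- function(litters, path) {
  utils::write.table(litters[, intersect(c("litter", "sow", "boar", "tnb",
                                           "nba", "nsb", "mum"), names(litters))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.scan_cols <- c("hap", "chrom", "start", "end", "freq", "expected",
                "observed", "p_value", "cxc_matings", "progeny",
                "het_carriers", "classification")

#' Write a scan results table
#'
#' Tab-separated output with one row per tested haplotype:
#' label, chromosome, window start/end, haplotype frequency, expected
#' and observed homozygotes, exact binomial p-value, number of
#' carrier-by-carrier matings, genotyped progeny of those matings,
#' heterozygous carrier progeny, and the MH/DH classification.
#' P-values are rendered in scientific notation with 3 significant
#' digits (e.g. `5.70E-10`), frequencies with 4 decimals and expected
#' counts with 2.
#'
#' @param records Scan record data frame (e.g. `as.data.frame()` of a
#'   [lethal_scan()] fit); an empty data frame yields a header-only
#'   file.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scan_table <- function(records, path) {
  records <- as.data.frame(records)
  fmt <- function(x, f) ifelse(is.na(x), "NA", sprintf(f, x))
  if (nrow(records)) {
    out <- data.frame(hap = if ("hap" %in% names(records)) records$hap else "",
                      chrom = records$chrom,
                      start = records$start, end = records$end,
                      freq = fmt(records$freq, "%.4f"),
                      expected = fmt(records$expected, "%.2f"),
                      observed = records$observed,
                      p_value = fmt(records$p_value, "%.2E"),
                      cxc_matings = records$cxc_matings,
                      progeny = records$progeny,
                      het_carriers = records$het_carriers,
                      classification = records$classification,
                      stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(setNames(rep(list(character(0)), length(.scan_cols)),
                                  .scan_cols))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scan results table written by [write_scan_table()]
#' @param path Path to the TSV.
#' @return A `data.frame` with numeric columns restored (to the
#'   printed precision).
#' @export
read_scan_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = c(hap = "character", chrom = "character",
                                        classification = "character"),
                         check.names = FALSE)
  for (cc in c("start", "end", "freq", "expected", "observed", "p_value",
               "cxc_matings", "progeny", "het_carriers"))
    d[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
  d
}

#' Read gene annotation intervals
#'
#' Reads gene intervals from BED (0-based half-open) or GFF3 (1-based
#' closed) and normalises both to 1-based closed coordinates, so the
#' same physical interval yields identical internal coordinates
#' regardless of dialect.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed"` or `"gff3"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`,
#'   `name` (1-based closed).
#' @export
read_gene_intervals <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(tolower(dialect[1]), c("bed", "gff3"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "bed") {
    start <- as.integer(vapply(f, `[`, "", 2L))
    end <- as.integer(vapply(f, `[`, "", 3L))
    if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) || any(end < 0L))
      stop("negative or non-numeric coordinate in BED input")
    out <- data.frame(chrom = vapply(f, `[`, "", 1L),
                      start = start + 1L,  # BED is 0-based half-open
                      end = end,
                      name = vapply(f, function(x) if (length(x) >= 4) x[[4]] else ".", ""),
                      stringsAsFactors = FALSE)
  } else {
    start <- as.integer(vapply(f, `[`, "", 4L))
    end <- as.integer(vapply(f, `[`, "", 5L))
    if (any(is.na(start)) || any(is.na(end)) || any(start < 1L) || any(end < 1L))
      stop("invalid coordinate in GFF3 input (must be 1-based positive)")
    attrs <- vapply(f, function(x) if (length(x) >= 9) x[[9]] else "", "")
    nm <- sub(".*Name=([^;]+).*", "\\1", attrs)
    noname <- !grepl("Name=", attrs)
    nm[noname] <- sub(".*ID=([^;]+).*", "\\1", attrs[noname])
    nm[noname & !grepl("ID=", attrs[noname])] <- "."
    out <- data.frame(chrom = vapply(f, `[`, "", 1L),
                      start = start, end = end, name = nm,
                      stringsAsFactors = FALSE)
  }
  out
}

#' Write gene intervals
#'
#' Inverse of [read_gene_intervals()]: writes 1-based closed internal
#' intervals in the requested dialect.
#'
#' @param x Data frame with `chrom`, `start`, `end`, `name` (1-based
#'   closed).
#' @param path Output path.
#' @param dialect `"bed"` or `"gff3"`.
#' @return Invisibly, `path`.
#' @export
write_gene_intervals <- function(x, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(tolower(dialect[1]), c("bed", "gff3"))
  if (dialect == "bed") {
    lines <- paste(x$chrom, x$start - 1L, x$end, x$name, sep = "\t")
  } else {
    lines <- paste(x$chrom, "lethalscan", "gene", x$start, x$end, ".", ".", ".",
                   paste0("Name=", x$name), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
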