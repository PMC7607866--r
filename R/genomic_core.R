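#' @import methods
#' @importFrom GenomicRanges GRanges reduce findOverlaps countOverlaps sort start end width seqnames strand mcols mcols<- resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats median quantile rgamma rnorm rbinom rexp runif rpois cor cor.test t.test wilcox.test p.adjust pt ppois pchisq coef sd var ks.test setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# ---- interval sets ---------------------------------------------------------

#' Construct a genomic interval set
#'
#' Intervals are held as an unstranded \code{GRanges}, the package's universal
#' coordinate currency. Internally all coordinates are 0-based half-open
#' \code{[start, end)}; because \code{GRanges} stores 1-based closed ranges,
#' conversion happens at construction and extraction only.
#'
#' @param chrom character vector of chromosome names (passed through verbatim;
#'   no "chr" normalization is attempted).
#' @param start,end integer vectors, 0-based half-open; \code{start < end}.
#' @param strand optional strand vector in \code{c("+", "-", "*")}.
#' @param ... further per-interval metadata columns (e.g. \code{score}).
#' @return a sorted \code{GRanges}.
#' @export
interval_set <- function(chrom, start, end, strand = NULL, ...) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be numeric and non-missing")
  if (any(start < 0)) stop("start must be >= 0")
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end for interval ", bad[1], " (", chrom[bad[1]], ":",
         start[bad[1]], "-", end[bad[1]], ")")
  if (is.null(strand)) strand <- "*"
  strand <- rep(strand, length.out = length(chrom))
  # keep chromosome order lexicographic so sorted output is reader-stable
  gr <- GenomicRanges::GRanges(factor(chrom, levels = sort(unique(chrom))),
                               IRanges::IRanges(start = start + 1, end = end),
                               strand = strand)
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' 0-based starts / exclusive ends of a GRanges
#' @param gr a \code{GRanges}.
#' @return numeric vector.
#' @export
start0 <- function(gr) GenomicRanges::start(gr) - 1

#' @rdname start0
#' @export
end0 <- function(gr) as.numeric(GenomicRanges::end(gr))

# ---- readers / writers -----------------------------------------------------

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom sizes file needs 2 columns: ", path)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a BED file into an interval set
#'
#' Accepts BED3/BED4/BED5 (tab-separated, no header). The 4th column is kept
#' as \code{name}, the 5th as \code{score}. BED coordinates are 0-based
#' half-open and read as-is; printed 1-based inclusive loci (the convention of
#' prose coordinates such as "chr12:4,106,500-4,164,700") are converted with
#' \code{one_based = TRUE}, which decrements starts by one.
#'
#' @param path file path.
#' @param one_based if \code{TRUE}, treat input starts as 1-based inclusive.
#' @return sorted unstranded \code{GRanges} (empty if the file is empty).
#' @export
read_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(interval_set(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path,
                        ": non-numeric coordinates")
  if (one_based) start <- start - 1
  bad <- which(start >= end)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path,
                        ": start >= end after conversion")
  args <- list(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) args$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) args$score <- as.numeric(vapply(fields, `[[`, "", 5))
  do.call(interval_set, args)
}

#' Write an interval set as BED
#'
#' Emits sorted BED3 (plus \code{name}/\code{score} columns when present),
#' 0-based half-open.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = format(start0(gr), scientific = FALSE, trim = TRUE),
                   end = format(end0(gr), scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% colnames(mc)) {
    df$name <- as.character(mc$name)
    if ("score" %in% colnames(mc)) df$score <- mc$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- binned tracks ---------------------------------------------------------

#' Construct a binned signal track
#'
#' A fixed-width binned, non-negative signal over a genome; the last bin of
#' each chromosome is truncated to the chromosome end.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param bin_width bin width in bp (default 100).
#' @param values optional named list of per-chromosome numeric vectors; when
#'   omitted an all-zero track is built.
#' @return an object of class \code{binned_track}.
#' @export
binned_track <- function(chrom_sizes, bin_width = 100, values = NULL) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  nbins <- ceiling(chrom_sizes / bin_width)
  if (is.null(values)) {
    values <- lapply(nbins, function(n) numeric(n))
  } else {
    values <- values[names(chrom_sizes)]
    ok <- mapply(function(v, n) length(v) == n, values, nbins)
    if (!all(ok)) stop("values have wrong bin counts for: ",
                       paste(names(chrom_sizes)[!ok], collapse = ", "))
    if (any(unlist(lapply(values, min), use.names = FALSE) < 0))
      stop("track values must be non-negative")
  }
  structure(list(chrom_sizes = chrom_sizes, bin_width = bin_width,
                 values = values),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", length(x$chrom_sizes), "chromosomes,",
      format(sum(x$chrom_sizes), big.mark = ","), "bp, bin width",
      x$bin_width, "bp\n")
  cat("  total signal:", format(track_total(x), digits = 6), "\n")
  invisible(x)
}

# actual (truncated) width of every bin on one chromosome
.bin_widths <- function(track, chrom) {
  n <- length(track$values[[chrom]])
  w <- rep(track$bin_width, n)
  w[n] <- track$chrom_sizes[[chrom]] - (n - 1) * track$bin_width
  w
}

#' Total signal mass of a track
#'
#' Sum over bins of value times actual bin width, divided by the nominal bin
#' width — i.e. the sum of bin values with the truncated last bin weighted by
#' its real width.
#'
#' @param track a \code{binned_track}.
#' @return scalar.
#' @export
track_total <- function(track) {
  s <- 0
  for (ch in names(track$values))
    s <- s + sum(track$values[[ch]] * .bin_widths(track, ch)) / track$bin_width
  s
}

#' Read a bedGraph file into a binned track
#'
#' Interval values are averaged, length-weighted, into fixed-width bins;
#' uncovered base pairs count as zero, so a record covering half a bin at
#' value 4 yields a bin value of 2.
#'
#' @param path bedGraph path (4 tab-separated columns, no header).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param bin_width bin width in bp.
#' @return a \code{binned_track}.
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_width = 100) {
  track <- binned_track(chrom_sizes, bin_width)
  df <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = c("character", "numeric",
                                                  "numeric", "numeric")),
                 error = function(e) NULL)
  if (is.null(df) || !nrow(df)) return(track)
  if (ncol(df) < 4) stop("bedGraph needs 4 columns: ", path)
  names(df) <- c("chrom", "start", "end", "value")
  if (any(df$value < 0)) stop("negative bedGraph value at line ",
                              which(df$value < 0)[1])
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown)) stop("unknown chromosome in bedGraph: ", unknown[1])
  over <- df$end > chrom_sizes[df$chrom]
  if (any(over)) stop("bedGraph interval beyond chromosome end at line ",
                      which(over)[1])
  if (any(df$start >= df$end)) stop("bedGraph start >= end at line ",
                                    which(df$start >= df$end)[1])
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    acc <- numeric(length(track$values[[ch]]))
    b0 <- floor(d$start / bin_width)
    b1 <- floor((d$end - 1) / bin_width)
    nb <- b1 - b0 + 1
    bin <- unlist(mapply(seq, b0, b1, SIMPLIFY = FALSE), use.names = FALSE)
    rec <- rep.int(seq_len(nrow(d)), nb)
    lo <- pmax(d$start[rec], bin * bin_width)
    hi <- pmin(d$end[rec], (bin + 1) * bin_width)
    mass <- d$value[rec] * (hi - lo)
    tab <- rowsum(mass, group = bin)
    acc[as.integer(rownames(tab)) + 1] <- tab[, 1]
    track$values[[ch]] <- acc / .bin_widths(track, ch)
  }
  track
}

#' Write a binned track as bedGraph
#'
#' One record per bin; zero bins are skipped.
#'
#' @param track a \code{binned_track}.
#' @param path output path.
#' @param digits significant digits for values.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    keep <- which(v != 0)
    if (!length(keep)) next
    s <- (keep - 1) * track$bin_width
    e <- pmin(keep * track$bin_width, track$chrom_sizes[[ch]])
    writeLines(paste(ch, format(s, scientific = FALSE, trim = TRUE),
                     format(e, scientific = FALSE, trim = TRUE),
                     signif(v[keep], digits), sep = "\t"), con)
  }
  invisible(path)
}

# ---- interval / track arithmetic ------------------------------------------

#' Flatten an interval set to its minimal disjoint cover
#'
#' Overlapping or book-ended intervals are merged; covered base pairs are
#' preserved. Idempotent.
#'
#' @param gr a \code{GRanges}.
#' @return disjoint sorted \code{GRanges}.
#' @export
flatten <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr, ignore.strand = TRUE),
                        ignore.strand = TRUE)
}

#' Total covered base pairs
#' @param gr a \code{GRanges}.
#' @return scalar bp.
#' @export
covered_bp <- function(gr) sum(as.numeric(GenomicRanges::width(flatten(gr))))

# signal mass (value * bp) of track over [0, p) positions, vectorized over p.
.prefix_mass <- function(track, chrom, p) {
  v <- track$values[[chrom]]
  w <- track$bin_width
  cs <- c(0, cumsum(v * .bin_widths(track, chrom)))
  b <- floor(p / w)                      # bin index containing p (0-based)
  b <- pmin(b, length(v) - 1)
  partial <- pmax(0, p - b * w)
  cs[b + 1] + v[b + 1] * pmin(partial, .bin_widths(track, chrom)[b + 1])
}

# vectorized signal mass over regions, with bounds checks
.region_mass <- function(track, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    if (!ch %in% names(track$values)) stop("unknown chromosome: ", ch)
    i <- which(chrom == ch)
    if (any(end[i] > track$chrom_sizes[[ch]]) || any(start[i] < 0))
      stop("region outside chromosome bounds on ", ch)
    out[i] <- .prefix_mass(track, ch, end[i]) - .prefix_mass(track, ch, start[i])
  }
  out
}

#' Length-weighted mean signal over regions
#'
#' Partial bins are weighted by their overlap with the region, so a constant
#' track returns the constant for any region.
#'
#' @param track a \code{binned_track}.
#' @param regions a \code{GRanges} (or a single region via \code{chrom},
#'   \code{start}, \code{end}).
#' @return numeric vector, one mean per region.
#' @export
mean_signal <- function(track, regions) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  s <- start0(regions); e <- end0(regions)
  .region_mass(track, chrom, s, e) / (e - s)
}

#' Aggregate signal over regions in bin units
#'
#' Sum of bin values overlapped by each region, partial bins contributing
#' proportionally to their overlap; equals \code{mean_signal * width /
#' bin_width}. Summing over a stitched domain equals summing over its
#' constituent bins: stitching never invents signal.
#'
#' @inheritParams mean_signal
#' @return numeric vector.
#' @export
region_signal <- function(track, regions) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  .region_mass(track, chrom, start0(regions), end0(regions)) / track$bin_width
}

#' Rebin a track to a coarser bin width
#'
#' The coarse value is the length-weighted mean of the fine bins it covers.
#'
#' @param track a \code{binned_track}.
#' @param bin_width new width, larger than the current one.
#' @return a \code{binned_track}.
#' @export
rebin <- function(track, bin_width) {
  if (bin_width < track$bin_width) stop("can only rebin to a coarser width")
  out <- binned_track(track$chrom_sizes, bin_width)
  for (ch in names(out$values)) {
    n <- length(out$values[[ch]])
    s <- (seq_len(n) - 1) * bin_width
    e <- pmin(seq_len(n) * bin_width, track$chrom_sizes[[ch]])
    out$values[[ch]] <- .region_mass(track, rep(ch, n), s, e) / (e - s)
  }
  out
}

#' Value of the bin containing each genomic position
#'
#' @param track a \code{binned_track}.
#' @param chrom chromosome name (scalar or vector).
#' @param pos 0-based positions.
#' @return numeric vector of bin values.
#' @export
signal_at <- function(track, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(track$values)) stop("unknown chromosome: ", ch)
    i <- which(chrom == ch)
    if (any(pos[i] < 0 | pos[i] >= track$chrom_sizes[[ch]]))
      stop("position outside chromosome bounds on ", ch)
    out[i] <- track$values[[ch]][floor(pos[i] / track$bin_width) + 1]
  }
  out
}

# ---- gene models -----------------------------------------------------------

#' Build gene models from a BED-like table
#'
#' @param chrom,start,end gene body coordinates (0-based half-open).
#' @param gene_id character ids.
#' @param strand "+" or "-"; the TSS is \code{start} for "+" genes and
#'   \code{end - 1} for "-" genes (5hmC itself is unstranded; strand is used
#'   only to derive the TSS and to orient metagene profiles).
#' @return a \code{GRanges} with \code{gene_id} and \code{tss} columns.
#' @export
gene_models <- function(chrom, start, end, gene_id, strand) {
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  tss <- ifelse(strand == "+", start, end - 1)
  interval_set(chrom, start, end, strand = strand,
               gene_id = gene_id, tss = tss)
}

#' Read gene models from a BED-like TSV
#'
#' Columns: chrom, start, end, gene_id, strand (BED6 order with the score
#' column absent or ignored).
#'
#' @param path file path.
#' @return a gene-model \code{GRanges}.
#' @export
read_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 6) df <- df[, c(1, 2, 3, 4, 6)]
  if (ncol(df) != 5) stop("gene table needs columns chrom,start,end,id,strand")
  gene_models(df[[1]], df[[2]], df[[3]], df[[4]], df[[5]])
}
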