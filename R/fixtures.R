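# Published count tables of a radish chromium(VI) stress root study
# (control library "CK" vs 200 mg/L Cr(VI) library "Cr200"), bundled as
# machine-readable fixtures. Raw counts and library totals are inputs; the
# printed normalized values, fold changes and calls serve as regression
# references for the package's own computations. Normalized values are
# kept as printed strings so their printed precision is known.

#' Bundled radish Cr(VI) stress study tables
#'
#' Returns the study's library totals, small RNA category accounting,
#' known miRNA family abundances, and the per-miRNA differential
#' expression tables (known and novel), transcribed from the published
#' report of a radish root small RNA sequencing experiment comparing a
#' control (CK) and a chromium-treated (Cr200) library.
#'
#' @return A list:
#' \describe{
#'   \item{totals}{named numeric, total clean reads: `CK`, `Cr200`.}
#'   \item{table1}{category accounting per library (`library`, `category`,
#'     `unique`, `unique_pct`, `total`, `total_pct`).}
#'   \item{table2}{known miRNA families (`family`, `conserved`,
#'     `n_members`, `reads_ck`, `reads_cr`, `norm_ck`, `norm_cr`, `log2fc`;
#'     `norm_*` as printed strings).}
#'   \item{table3}{known differentially expressed miRNAs (`family`,
#'     `mirna_id`, `count_ck`, `count_tr`, `norm_ck`, `norm_tr`, `log2fc`,
#'     `pvalue`, `sig`, `direction`).}
#'   \item{table4}{novel differentially expressed miRNAs (`mirna_id`,
#'     `sequence`, `count_ck`, `count_tr`, `norm_ck`, `norm_tr`, `log2fc`,
#'     `pvalue`, `sig`, `direction`).}
#' }
#' @examples
#' tab <- radish_cr_tables()
#' tab$totals
#' subset(tab$table3, mirna_id == "miR156a")
#' @export
radish_cr_tables <- function() {
  totals <- c(CK = 18127561, Cr200 = 19552260)

  t1 <- function(library, category, unique, unique_pct, total, total_pct) {
    data.frame(library = library, category = category, unique = unique,
               unique_pct = unique_pct, total = total, total_pct = total_pct,
               stringsAsFactors = FALSE)
  }
  table1 <- rbind(
    t1("CK", "total", 3360437, 100, 18127561, 100),
    t1("CK", "miRNA", 20156, 0.60, 1680180, 9.27),
    t1("CK", "rRNA", 68092, 2.02, 1333046, 7.36),
    t1("CK", "snRNA", 4561, 0.14, 17456, 0.10),
    t1("CK", "snoRNA", 2399, 0.07, 4918, 0.03),
    t1("CK", "tRNA", 6374, 0.19, 162311, 0.90),
    t1("CK", "unannotated", 3258855, 96.98, 14929650, 82.36),
    t1("Cr200", "total", 6172992, 100, 19552260, 100),
    t1("Cr200", "miRNA", 43980, 0.71, 2057888, 10.53),
    t1("Cr200", "rRNA", 101446, 1.64, 2552322, 13.05),
    t1("Cr200", "snRNA", 10311, 0.17, 48852, 0.25),
    t1("Cr200", "snoRNA", 2979, 0.05, 6596, 0.03),
    t1("Cr200", "tRNA", 12242, 0.20, 260269, 1.33),
    t1("Cr200", "unannotated", 6002034, 97.23, 14626333, 74.81)
  )

  t2 <- function(family, n, ck, cr, nck, ncr, fc, conserved) {
    data.frame(family = family, conserved = conserved, n_members = n,
               reads_ck = ck, reads_cr = cr, norm_ck = nck, norm_cr = ncr,
               log2fc = fc, stringsAsFactors = FALSE)
  }
  cons <- rbind(
    t2("miR156/157", 5, 366511, 265213, "20218.44", "13564.31", -0.58, TRUE),
    t2("miR158", 2, 699489, 1730976, "38587.04", "88530.74", 1.20, TRUE),
    t2("miR159", 1, 2645, 1201, "145.91", "61.43", -1.25, TRUE),
    t2("miR160", 4, 2652, 1644, "146.30", "84.08", -0.80, TRUE),
    t2("miR161", 1, 0, 151, "0.01", "7.72", 9.59, TRUE),
    t2("miR162", 1, 750, 1438, "41.37", "73.55", 0.83, TRUE),
    t2("miR164", 2, 20482, 36698, "1129.88", "1876.92", 0.73, TRUE),
    t2("miR165/166", 5, 91078, 250786, "5024.28", "12826.45", 1.35, TRUE),
    t2("miR167", 2, 19807, 21945, "1092.65", "1122.38", 0.04, TRUE),
    t2("miR168", 2, 196680, 86888, "10849.78", "4443.89", -1.29, TRUE),
    t2("miR169", 4, 9690, 4742, "534.55", "242.53", -1.14, TRUE),
    t2("miR171", 1, 155, 299, "8.55", "15.29", 0.84, TRUE),
    t2("miR172", 2, 1024, 16755, "56.49", "856.93", 3.92, TRUE),
    t2("miR319", 2, 13971, 8927, "770.70", "456.57", -0.76, TRUE),
    t2("miR390", 2, 324, 6464, "17.87", "330.60", 4.21, TRUE),
    t2("miR391", 2, 1066, 2988, "58.81", "152.82", 1.38, TRUE),
    t2("miR393", 1, 15, 13, "0.83", "0.66", -0.32, TRUE),
    t2("miR394", 2, 201, 946, "11.09", "48.38", 2.13, TRUE),
    t2("miR395", 2, 71, 247, "3.92", "12.63", 1.69, TRUE),
    t2("miR396", 2, 958, 2301, "52.85", "117.68", 1.16, TRUE),
    t2("miR397", 1, 15201, 927, "838.56", "47.41", -4.14, TRUE),
    t2("miR398", 3, 1934, 64, "106.69", "3.27", -5.03, TRUE),
    t2("miR399", 2, 142, 87, "7.83", "4.45", -0.82, TRUE),
    t2("miR408", 1, 266952, 32197, "14726.31", "1646.72", -3.16, TRUE)
  )
  noncons <- rbind(
    t2("miR400", 1, 109, 84, "6.01", "4.30", -0.49, FALSE),
    t2("miR403", 1, 1634, 1825, "90.14", "93.34", 0.05, FALSE),
    t2("miR414", 1, 344, 0, "18.98", "0.01", -10.89, FALSE),
    t2("miR415", 1, 0, 229, "0.01", "11.71", 10.19, FALSE),
    t2("miR482", 1, 134, 2254, "7.39", "115.28", 3.96, FALSE),
    t2("miR535", 2, 34, 2034, "1.88", "104.03", 5.79, FALSE),
    t2("miR824", 2, 529, 2477, "29.18", "126.69", 2.12, FALSE),
    t2("miR825", 1, 1455, 1835, "80.26", "93.85", 0.23, FALSE),
    t2("miR827", 1, 275, 509, "15.17", "26.03", 0.78, FALSE),
    t2("miR845", 2, 3003, 5968, "165.66", "305.23", 0.88, FALSE),
    t2("miR854", 1, 229, 387, "12.63", "19.79", 0.65, FALSE),
    t2("miR857", 1, 1413, 240, "77.95", "12.27", -2.67, FALSE),
    t2("miR858", 2, 23, 13, "1.27", "0.66", -0.93, FALSE),
    t2("miR860", 1, 58, 345, "3.20", "17.65", 2.46, FALSE),
    t2("miR1885", 1, 5417, 6787, "298.83", "347.12", 0.22, FALSE),
    t2("miR2111", 3, 280, 104, "15.45", "5.32", -1.54, FALSE),
    t2("miR2118", 1, 27628, 23077, "1524.09", "1180.27", -0.37, FALSE),
    t2("miR4993", 1, 0, 306, "0.01", "15.65", 10.61, FALSE),
    t2("miR5265", 1, 0, 261, "0.01", "13.35", 10.38, FALSE),
    t2("miR5293", 1, 143, 551, "7.89", "28.18", 1.84, FALSE),
    t2("miR5671", 1, 0, 3860, "0.01", "197.42", 14.27, FALSE),
    t2("miR7767", 2, 9153, 23835, "504.92", "1219.04", 1.27, FALSE)
  )
  table2 <- rbind(cons, noncons)

  t3 <- function(family, id, ck, cr, nck, ncr, fc, p, sig, dir) {
    data.frame(family = family, mirna_id = id, count_ck = ck, count_tr = cr,
               norm_ck = nck, norm_tr = ncr, log2fc = fc, pvalue = p,
               sig = sig, direction = dir, stringsAsFactors = FALSE)
  }
  table3 <- rbind(
    t3("miR156/157", "miR156a", 94427, 59654, "5209.0295", "3051.0028", -0.77, "0", "", "down"),
    t3("miR156/157", "miR156a-3p", 257, 0, "14.1773", "0.0100", -10.47, "2.10E-82", "**", "down"),
    t3("miR156/157", "miR156f-3p", 0, 286, "0.0100", "14.6275", 10.51, "3.36E-82", "**", "up"),
    t3("miR156/157", "miR157a", 268528, 202820, "14813.2449", "10373.2254", -0.51, "0", "", "down"),
    t3("miR156/157", "miR157a-3p", 3299, 2453, "181.9881", "125.4586", -0.54, "9.42E-45", "", "down"),
    t3("miR159", "miR159a", 2645, 1201, "145.9104", "61.4251", -1.25, "9.43E-148", "**", "down"),
    t3("miR160", "miR160a", 0, 411, "0.0100", "21.0206", 11.04, "8.12E-118", "**", "up"),
    t3("miR160", "miR160b", 80, 0, "4.4132", "0.0100", -8.79, "3.66E-26", "**", "down"),
    t3("miR160", "miR160b-3p", 2572, 0, "141.8834", "0.0100", -13.79, "0", "**", "down"),
    t3("miR160", "miR160d-3p", 0, 1233, "0.0100", "63.0618", 12.62, "0", "**", "up"),
    t3("miR161", "miR161", 0, 151, "0.0100", "7.7229", 9.59, "9.81E-44", "**", "up"),
    t3("miR164", "miR164b-3p", 130, 42, "7.1708", "2.1481", -1.74, "2.24E-13", "**", "down"),
    t3("miR165/166", "miR165a", 1978, 11721, "109.1156", "599.4703", 2.46, "0", "**", "up"),
    t3("miR165/166", "miR165a-3p", 173, 10692, "9.5435", "546.8422", 5.84, "0", "**", "up"),
    t3("miR165/166", "miR166e-3p", 0, 1029, "0.0100", "52.6282", 12.36, "6.65E-294", "**", "up"),
    t3("miR165/166", "miR166g-3p", 285, 0, "15.7219", "0.0100", -10.62, "2.66E-91", "**", "down"),
    t3("miR168", "miR168a", 195230, 85348, "10769.7886", "4365.1220", -1.30, "0", "**", "down"),
    t3("miR169", "miR169b", 884, 0, "48.7655", "0.0100", -12.25, "1.24E-281", "**", "down"),
    t3("miR169", "miR169j-3p", 0, 819, "0.0100", "41.8877", 12.03, "4.55E-234", "**", "up"),
    t3("miR169", "miR169m", 0, 3923, "0.0100", "200.6418", 14.29, "0", "**", "up"),
    t3("miR169", "miR169r-3p", 8806, 0, "485.7796", "0.0100", -15.57, "0", "**", "down"),
    t3("miR172", "miR172c", 1024, 16685, "56.4886", "853.3540", 3.92, "0", "**", "up"),
    t3("miR172", "miR172e-3p", 0, 70, "0.01", "3.5801", 8.48, "1.18E-20", "**", "up"),
    t3("miR319", "miR319a-3p", 710, 219, "39.1669", "11.2008", -1.81, "1.17E-69", "**", "down"),
    t3("miR319", "miR319b-5p", 13261, 8708, "731.538", "445.3705", -0.72, "2.73E-290", "", "down"),
    t3("miR390", "miR390a", 314, 6289, "17.3217", "321.6508", 4.21, "0", "**", "up"),
    t3("miR390", "miR390a-3p", 10, 175, "0.5516", "8.9504", 4.02, "1.07E-37", "**", "up"),
    t3("miR391", "miR391-3p", 0, 21, "0.0100", "1.0740", 6.75, "1.08E-06", "**", "up"),
    t3("miR394", "miR394a", 14, 613, "0.7723", "31.3519", 5.34, "1.21E-151", "**", "up"),
    t3("miR395", "miR395a", 71, 0, "3.9167", "0.0100", -8.61, "2.65E-23", "**", "down"),
    t3("miR395", "miR395b", 0, 247, "0.0100", "12.6328", 10.30, "4.35E-71", "**", "up"),
    t3("miR397", "miR397a", 15201, 927, "838.5574", "47.4114", -4.14, "0", "**", "down"),
    t3("miR398", "miR398b-3p", 133, 0, "7.3369", "0.0100", -9.52, "5.28E-43", "**", "down"),
    t3("miR398", "miR398b-5p", 0, 64, "0.0100", "3.2733", 8.35, "6.03E-19", "**", "up"),
    t3("miR398", "miR398c-5p", 1801, 0, "99.3515", "0.0100", -13.28, "0", "**", "down"),
    t3("miR399", "miR399b", 0, 87, "0.0100", "4.4496", 8.80, "1.69E-25", "**", "up"),
    t3("miR399", "miR399h-5p", 142, 0, "7.8334", "0.0100", -9.61, "7.29E-46", "**", "down"),
    t3("miR408", "miR408-5p", 266952, 32197, "14726.3054", "1646.7150", -3.16, "0", "**", "down"),
    t3("miR414", "miR414", 344, 0, "18.9766", "0.0100", -10.89, "4.76E-110", "**", "down"),
    t3("miR415", "miR415", 0, 229, "0.0100", "11.71", 10.19, "5.85E-66", "**", "up"),
    t3("miR482", "miR482a-5p", 134, 2254, "7.3921", "115.2808", 3.96, "0", "**", "up"),
    t3("miR535", "miR535b", 0, 2034, "0.01", "104.0289", 13.34, "0", "**", "up"),
    t3("miR535", "miR535d", 34, 0, "1.8756", "0.0100", -7.55, "1.51E-11", "**", "down"),
    t3("miR824", "miR824-3p", 109, 1565, "6.0129", "80.0419", 3.73, "1.57E-307", "**", "up"),
    t3("miR845", "miR845d", 1282, 74, "70.7148", "3.7847", -4.22, "9.51E-306", "**", "down"),
    t3("miR857", "miR857", 1413, 240, "77.9407", "12.2748", -2.67, "4.08E-222", "**", "down"),
    t3("miR860", "miR860", 58, 345, "3.1995", "17.645", 2.46, "2.01E-46", "**", "up"),
    t3("miR2111", "miR2111a-3p", 140, 0, "7.7230", "0.0100", -9.59, "3.15E-45", "**", "down"),
    t3("miR2111", "miR2111a-5p", 140, 61, "7.7230", "3.1198", -1.31, "7.17E-10", "**", "down"),
    t3("miR2111", "miR2111b-3p", 0, 43, "0.0100", "2.1992", 7.78, "5.81E-13", "**", "up"),
    t3("miR4993", "miR4993", 0, 306, "0.0100", "15.6504", 10.61, "6.72E-88", "**", "up"),
    t3("miR5265", "miR5265", 0, 261, "0.0100", "13.3488", 10.38, "4.46E-75", "**", "up"),
    t3("miR5293", "miR5293", 143, 771, "7.8885", "39.4328", 2.29, "5.15E-51", "**", "up"),
    t3("miR5671", "miR5671", 0, 3860, "0.0100", "197.42", 14.27, "0", "**", "up")
  )

  t4 <- function(id, seq, ck, nck, cr, ncr, fc, p, sig, dir) {
    data.frame(mirna_id = id, sequence = seq, count_ck = ck, count_tr = cr,
               norm_ck = nck, norm_tr = ncr, log2fc = fc, pvalue = p,
               sig = sig, direction = dir, stringsAsFactors = FALSE)
  }
  table4 <- rbind(
    t4("rsa-miRn-1", "AAAUCAUACUUUCAUUGAUA", 277, "15.2806", 0, "0.0100", -10.58, "9.26E-89", "**", "down"),
    t4("rsa-miRn-2", "UGGAUAUGAUGUAGUUGAUCCGA", 1275, "70.3349", 0, "0.0100", -12.78, "0", "**", "down"),
    t4("rsa-miRn-3", "AGCAAACGAGAAUUGAACGGA", 419, "23.1140", 192, "9.8198", -1.24, "1.78E-24", "**", "down"),
    t4("rsa-miRn-10", "UGGAUGUAGAGGCAUUUCUUC", 79, "4.3580", 0, "0.0100", -8.77, "7.60E-26", "**", "down"),
    t4("rsa-miRn-12", "ACATTGGACTACATATATTAC", 81, "4.4683", 935, "47.8206", 3.42, "2.09E-171", "**", "up"),
    t4("rsa-miRn-14", "CGUACGAGGAGCCAAGCAUGA", 833, "45.9521", 0, "0.0100", -12.17, "1.99E-265", "**", "down"),
    t4("rsa-miRn-19", "GCUCAAGAAAGCUGUGGGAAA", 155, "8.5505", 0, "0.0100", -9.74, "5.40E-50", "**", "down"),
    t4("rsa-miRn-20", "UCCCUUUGGAUGUCGUCUUGUG", 20, "1.1033", 0, "0.0100", -6.79, "4.25E-07", "**", "down"),
    t4("rsa-miRn-23", "UCAAUGAAAGGUAUGAUUCCC", 0, "0.0100", 377, "19.2817", 10.91, "3.96E-108", "**", "up"),
    t4("rsa-miRn-28", "GGUCUUUGGGAGUUGGAUUAUCAUC", 0, "0.0100", 856, "43.7801", 12.10, "1.31E-244", "**", "up"),
    t4("rsa-miRn-44", "CGGUGGUGGAGGUGGAGGCGG", 0, "0.0100", 46, "2.3527", 7.88, "8.12E-14", "**", "up"),
    t4("rsa-miRn-45", "UCAGCCGAGGUUCCAUUACCAC", 0, "0.0100", 206, "10.5359", 10.04, "2.09E-59", "**", "up"),
    t4("rsa-miRn-46", "UGUUUUGUGCGUGAAUCUAAUU", 0, "0.0100", 48, "2.4550", 7.94, "2.18E-14", "**", "up"),
    t4("rsa-miRn-47", "CGAAGUGACUUAUAAUGAUCU", 0, "0.0100", 32, "1.6366", 7.35, "7.91E-10", "**", "up"),
    t4("rsa-miRn-54", "AGGAUUGAGUCUAGAAGCAUA", 0, "0.0100", 125, "6.3931", 9.32, "2.51E-36", "**", "up"),
    t4("rsa-miRn-55", "UGGAUACAGUGAUGAUGACGAU", 0, "0.0100", 20, "1.0229", 6.68, "2.08E-06", "**", "up")
  )

  list(totals = totals, table1 = table1, table2 = table2,
       table3 = table3, table4 = table4)
}
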