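# Fixture builders. Records are built in code; no data files.

# a clean record with every item at the given level(s) per scale
make_record <- function(code = "r1", wave = "T1",
                        levels = c(phq = 1, gad = 1, rrs = 2, anis = 3,
                                   atq = 3),
                        rt_s = 900, lie_ok = TRUE, age = 20, grade = 2,
                        sex = "female", residence = "urban") {
  rec <- data.frame(code = code, wave = wave, stringsAsFactors = FALSE)
  for (sc in default_scales())
    for (col in item_columns(sc))
      rec[[col]] <- unname(levels[[sc$name]])
  rec$rt_s <- rt_s; rec$lie_ok <- lie_ok
  rec$age <- age; rec$grade <- grade
  rec$sex <- sex; rec$residence <- residence
  rec
}

make_records <- function(n, codes = sprintf("r%02d", seq_len(n)), ...) {
  do.call(rbind, lapply(codes, function(cd) make_record(code = cd, ...)))
}

# the five-record validity-filter fixture: one record per exclusion
# reason plus one clean record. Reference outlier statistics put
# record D far outside the norm (scores sit near the means given by
# `levels`, so a reference of mean = clean total, sd = 1 makes a
# +10-point shift a > 3 sd outlier).
qc_fixture <- function() {
  a <- make_record("A", lie_ok = FALSE)
  b <- make_record("B"); b$phq_3 <- NA
  c <- make_record("C", rt_s = 400)
  d <- make_record("D"); d[paste0("anis_", 1:10)] <- 4   # +10 on NAB
  e <- make_record("E")
  recs <- rbind(a, b, c, d, e)
  clean <- score_records(make_record("ref"))
  ref <- lapply(construct_labels(), function(lab) c(clean[[lab]], 1))
  names(ref) <- construct_labels()
  list(records = recs, config = qc_config(outlier_ref = ref))
}
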