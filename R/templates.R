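# Frozen morphotype template coefficients.
# GENERATED by scripts/tune_templates.R -- edit that script, not this file.
# Each entry: normalized 8x4 elliptic Fourier coefficients (columns A, B,
# C, D), the harmonic-1 semi-major axis in mm implied by the nominal seed
# length, and the tuning targets.

.seed_templates <- list(
  heben_like = list(
    coeffs = matrix(c(
      1, 1.08086879687616e-19, 2.30934515616749e-20, 0.664282625346406,
      0.023260204108665, -0.00593430772679035, -0.0131240189440438, -0.0930967201365684,
      0.0705415074864566, -0.00324123050013897, -0.00565653304441885, 0.0117924500180328,
      0.0303037912720529, -0.00525655274920404, 0.00269206781759007, 0.0158437581732556,
      0.0188538313414424, -0.00121235119399808, 0.00334862038139986, 0.0248598609804832,
      0.00806140631894039, -0.000532195812338285, 0.00270327156812091, 0.0141456420689563,
      0.00158725483887798, 0.000493805761586571, 0.00161459298543162, 0.0101269884299034,
      0.00133830142220158, -8.51653590295706e-05, 0.00107491794179251, 0.00578689897999158
    ), nrow = 8, byrow = TRUE,
    dimnames = list(NULL, c("A", "B", "C", "D"))),
    size_mm = 3.12692223281246,
    nominal_length_mm = 6.5,
    target_solidity = 975L,
    target_aspect_ratio = 1.62
  ),
  chenin_like = list(
    coeffs = matrix(c(
      1, -1.72565949663055e-19, 4.1007608744008e-20, 0.630059402588348,
      0.0121438100278388, -0.00887959884626422, -0.0211933524421495, -0.102856312616779,
      0.0749004670532738, -0.00542080455031297, -0.0104338478916446, 0.00312284249601602,
      0.0318596802090576, -0.0090984882920976, 0.0014645680932913, 0.00577853996992834,
      0.0253727954047897, -0.00292935295074399, 0.00439426206782397, 0.0266080714359345,
      0.012673176490288, -0.00197092055780898, 0.00487288706011679, 0.0176173156615011,
      0.00281170202278167, 0.000951089925893924, 0.00430646456438392, 0.0165607519255366,
      0.00133259688846951, 0.000225396396034413, 0.00363505144191134, 0.0107110379973206
    ), nrow = 8, byrow = TRUE,
    dimnames = list(NULL, c("A", "B", "C", "D"))),
    size_mm = 3.2971624001562,
    nominal_length_mm = 6.8,
    target_solidity = 955L,
    target_aspect_ratio = 1.68
  ),
  sylvestris_like = list(
    coeffs = matrix(c(
      1, -7.24949498233315e-20, 1.95477728082984e-20, 0.815769872075257,
      0.0120942517627202, -0.00318208924576763, -0.00507023913312963, -0.0257285306770803,
      0.0398781218854545, -0.00239146816498706, -0.00376450240811486, 0.0131239543930804,
      0.014278813902593, -0.00367430709284721, -0.000621794329021502, 0.000221871797270632,
      0.0120347191805124, -0.00257129780015028, 0.000487656661705076, 0.00553637047329458,
      0.00670472225551551, -0.00189371910840484, 0.0011267167880604, 0.00418783255163692,
      0.0025891953844388, -0.000608211819730323, 0.00152679890060955, 0.00494974066950384,
      0.00125275937156508, -0.000288561963800834, 0.00105779899548835, 0.00293600566487161
    ), nrow = 8, byrow = TRUE,
    dimnames = list(NULL, c("A", "B", "C", "D"))),
    size_mm = 2.66788522047038,
    nominal_length_mm = 5.5,
    target_solidity = 1000L,
    target_aspect_ratio = 1.3
  )
)
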