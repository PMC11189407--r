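Drop zone for the real Poznań inputs (not redistributed with the package):

* `births.csv` — the deposited monthly birth register
  (Mendeley Data, DOI 10.17632/n4jdgfxmwv.1), any delimited layout with
  year, month and the two sex-specific count columns
  (`read_birth_table()` maps common column names, or pass `col_map`).
* `temperatures.csv` — the Kolendowicz et al. homogenized monthly mean
  temperature series 1848-1900, long (year, month, temp) or wide
  (year x 12 months) layout.

With both files in place, reinstall the package; the reproduction test in
`tests/testthat/test-acceptance.R` then checks the register totals, the
station climatology, and the published model estimates.
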