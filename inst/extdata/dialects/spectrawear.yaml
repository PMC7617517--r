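device: "SpectraWear"
manufacturer: "University of Manchester"
delimiter: "\t"
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["datetime"]
  format: "%Y-%m-%d %H:%M:%S"
  timezone: supplied
id_column: "participant"
channels:
  - column: "mEDI"
    channel: "MEDI"
    unit: "mel-EDI lx"
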