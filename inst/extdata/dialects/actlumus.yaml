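device: "ActLumus"
manufacturer: "Condor Instruments"
delimiter: ";"
skip: 0
header: true
decimal_mark: ","
datetime:
  columns: ["DATE/TIME"]
  format: "%d/%m/%Y %H:%M:%S"
  timezone: supplied
id_column: null
channels:
  - column: "MEDI"
    channel: "MEDI"
    unit: "mel-EDI lx"
  - column: "LIGHT"
    channel: "lux"
    unit: "lx"
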