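device: "VEET"
manufacturer: "Meta Reality Labs"
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["time_stamp"]
  format: null
  timezone: unix_ms
id_column: null
channels:
  - column: "ALS_lux"
    channel: "lux"
    unit: "lx"
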