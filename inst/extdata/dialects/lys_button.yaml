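device: "LYS Button"
manufacturer: "LYS Technologies"
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["timestamp"]
  format: null
  timezone: unix
id_column: "device_id"
channels:
  - column: "lux"
    channel: "lux"
    unit: "lx"
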