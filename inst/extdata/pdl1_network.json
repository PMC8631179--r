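{
  "temperature_K": 310,
  "c0": 1,
  "states": [
    {
      "id": "S1",
      "nu": 2,
      "g_bind_total": -23.63
    },
    {
      "id": "S2",
      "nu": 2,
      "g_bind_total": -31.15
    },
    {
      "id": "S3",
      "nu": 2,
      "g_bind_total": -43.97
    }
  ],
  "transitions": [
    {
      "id": "T1",
      "g_monomer": 0,
      "links": [
        {
          "state": "S1",
          "A": 1
        },
        {
          "state": "S2",
          "A": 1
        },
        {
          "state": "S3",
          "A": 1
        }
      ]
    },
    {
      "id": "T2",
      "g_monomer": -5.435,
      "links": [
        {
          "state": "S2",
          "A": 1
        },
        {
          "state": "S3",
          "A": 1
        }
      ]
    }
  ]
}
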