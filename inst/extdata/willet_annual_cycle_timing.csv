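stage,nj,ma_south,ma_north_me
fall_migration_departure,192.3,215.2,207.1
winter_arrival,215.7,231.4,223.7
spring_migration_departure,94.1,107.4,109.9
breeding_site_arrival,107.1,121.2,127.0
nest_initiation,127.4,139.1,145.8
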