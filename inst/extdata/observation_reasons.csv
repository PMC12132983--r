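sign,category,code,count
temperature,skip,forgot,8
temperature,skip,checked_hot_only,5
temperature,skip,no_thermometer,1
temperature,insufficient,thermo_distance,102
temperature,insufficient,thermo_location,88
temperature,insufficient,thermo_read_too_soon,16
muac,skip,not_necessary,16
muac,skip,child_too_old,7
muac,skip,copied_health_card,6
muac,skip,reused_previous_day,1
muac,skip,child_agitated,1
muac,insufficient,ribbon_location,111
muac,insufficient,child_too_young,10
muac,insufficient,ribbon_too_tight,5
muac,insufficient,ribbon_over_clothes,2
muac,insufficient,ribbon_too_loose,1
weight,skip,not_necessary,14
weight,skip,copied_health_card,9
weight,skip,reused_previous_day,1
weight,skip,child_agitated,1
weight,insufficient,heavy_clothes,117
weight,insufficient,wearing_shoes,83
weight,insufficient,partially_supported,13
weight,insufficient,balance_not_calibrated,3
weight,insufficient,holding_objects,3
height,skip,no_meter,13
height,skip,not_necessary,11
height,skip,estimated_visually,11
height,skip,agitated_or_injured,4
height,skip,reused_previous_day,1
height,insufficient,shoes_or_hat,62
height,insufficient,not_touching_surface,53
height,insufficient,not_looking_straight,25
height,insufficient,meter_not_straight,12
height,insufficient,bad_zero_or_meter,5
heart_rate,skip,not_necessary,22
heart_rate,skip,too_time_consuming,17
heart_rate,skip,oximeter_broken,4
heart_rate,skip,child_agitated,4
heart_rate,skip,forgot,2
heart_rate,skip,referral_urgent,1
heart_rate,insufficient,captor_unavailable,15
heart_rate,insufficient,captor_position,14
spo2,skip,not_necessary,16
spo2,skip,too_time_consuming,11
spo2,skip,oximeter_broken,4
spo2,skip,child_agitated,4
spo2,skip,forgot,2
spo2,skip,referral_urgent,1
spo2,insufficient,captor_unavailable,15
spo2,insufficient,captor_position,14
resp_rate,skip,not_necessary,35
resp_rate,skip,too_time_consuming,16
resp_rate,skip,forgot,10
resp_rate,skip,child_agitated,5
resp_rate,skip,no_timer_or_app,3
resp_rate,skip,used_oximeter,2
resp_rate,skip,referral_urgent,1
resp_rate,insufficient,underestimation,7
resp_rate,insufficient,abdomen_not_uncovered,6
resp_rate,insufficient,forgot_value,5
resp_rate,insufficient,not_full_minute,4
resp_rate,insufficient,child_agitated,3
resp_rate,insufficient,timer_not_reset,3
resp_rate,insufficient,overestimation,2
resp_rate,insufficient,child_standing,2
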