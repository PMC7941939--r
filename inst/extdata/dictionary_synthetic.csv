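harmonised_name,source,stage,dtype,unit,description,site,raw_name,unit_rule,recode_map,binary_mode,categories
mat_h_dod,mat,harmonised,date,date,Date of delivery,all,dod,date,,,
mat_h_ga,mat,harmonised,continuous,days,Gestational age at birth in completed days,alpha,GestationAtDelivery,ga_to_days,,,
mat_h_ga,mat,harmonised,continuous,days,Gestational age at birth in completed days,bravo,gest_wks,ga_to_days,,,
mat_h_ga,mat,harmonised,continuous,days,Gestational age at birth in completed days,charlie,ga_days,ga_to_days,,,
mat_h_height,mat,harmonised,continuous,m,Maternal height,alpha,HeightCm,cm_to_m,,,
mat_h_height,mat,harmonised,continuous,m,Maternal height,bravo,height_ftin,ftin_to_m,,,
mat_h_height,mat,harmonised,continuous,m,Maternal height,charlie,height_m,numeric,,,
mat_h_weight,mat,harmonised,continuous,kg,Maternal booking weight,alpha,WeightKg,numeric,,,
mat_h_weight,mat,harmonised,continuous,kg,Maternal booking weight,bravo,weight_stlb,stlb_to_kg,,,
mat_h_weight,mat,harmonised,continuous,kg,Maternal booking weight,charlie,weight_kg,numeric,,,
mat_h_ethnicity,mat,harmonised,categorical,,Maternal ethnic group,alpha,Ethnicity,identity,White British=>White|White Other=>White|Black African=>Black|Black Caribbean=>Black|Asian - Indian=>Asian|Asian - Other=>Asian|Mixed=>Mixed|Any Other=>Other,,White|Black|Asian|Mixed|Other
mat_h_ethnicity,mat,harmonised,categorical,,Maternal ethnic group,bravo,ethnic_group,identity,British=>White|Irish=>White|White other=>White|African=>Black|Caribbean=>Black|Indian=>Asian|Pakistani=>Asian|Chinese=>Asian|Mixed background=>Mixed|Other group=>Other,,White|Black|Asian|Mixed|Other
mat_h_ethnicity,mat,harmonised,categorical,,Maternal ethnic group,charlie,ethnicity_code,identity,WB=>White|WO=>White|BA=>Black|BC=>Black|AI=>Asian|AO=>Asian|MX=>Mixed|OT=>Other,,White|Black|Asian|Mixed|Other
mat_h_modebirth,mat,harmonised,categorical,,Mode of birth,alpha,DeliveryMode,identity,SVD=>unassisted vaginal|Ventouse=>assisted vaginal|Forceps=>assisted vaginal|Em LSCS=>caesarean section|El LSCS=>caesarean section,,unassisted vaginal|assisted vaginal|caesarean section
mat_h_modebirth,mat,harmonised,categorical,,Mode of birth,bravo,birth_method,identity,Normal Delivery=>unassisted vaginal|Instrumental - Ventouse=>assisted vaginal|Instrumental - Forceps=>assisted vaginal|Emergency Caesarean=>caesarean section|Elective Caesarean=>caesarean section,,unassisted vaginal|assisted vaginal|caesarean section
mat_h_modebirth,mat,harmonised,categorical,,Mode of birth,charlie,mode_del,identity,spont vertex=>unassisted vaginal|ventouse del=>assisted vaginal|forceps del=>assisted vaginal|lscs emergency=>caesarean section|lscs elective=>caesarean section,,unassisted vaginal|assisted vaginal|caesarean section
mat_h_parity,mat,harmonised,continuous,count,Number of previous births,alpha,Parity,numeric,,,
mat_h_parity,mat,harmonised,continuous,count,Number of previous births,bravo,para,numeric,,,
mat_h_multiparous,mat,harmonised,binary,,Multiparity flag (sites supplying parity only as a binary group),charlie,parity_group,identity,Multiparous=>yes|Nulliparous=>no,full,yes|no
mat_h_chronichtn,mat,harmonised,binary,,Pre-existing hypertension,alpha,ChronicHTN,identity,Y=>yes|N=>no,full,yes|no
mat_h_chronichtn,mat,harmonised,binary,,Pre-existing hypertension,bravo,htn_chronic,identity,Yes=>yes|No=>no,full,yes|no
mat_h_chronichtn,mat,harmonised,binary,,Pre-existing hypertension,charlie,pet_htn,identity,1=>yes,affirmative_only,yes|no
mat_h_epidurallab,mat,harmonised,binary,,Epidural recorded in labour analgesia,alpha,LabourAnalgesia,identity,Epidural=>yes|Entonox=>no|Pethidine=>no|None=>no,full,yes|no
mat_h_epidurallab,mat,harmonised,binary,,Epidural recorded in labour analgesia,bravo,analgesia_labour,identity,EPIDURAL=>yes|GAS & AIR=>no|TENS=>no|NIL=>no,full,yes|no
mat_h_epidurallab,mat,harmonised,binary,,Epidural recorded in labour analgesia,charlie,epidural_flag,identity,1=>yes,affirmative_only,yes|no
mat_h_epiduralbirth,mat,harmonised,binary,,Epidural recorded in birth analgesia,alpha,BirthAnalgesia,identity,Epidural=>yes|Entonox=>no|Pethidine=>no|None=>no,full,yes|no
mat_h_epiduralbirth,mat,harmonised,binary,,Epidural recorded in birth analgesia,bravo,analgesia_birth,identity,EPIDURAL=>yes|GAS & AIR=>no|TENS=>no|NIL=>no,full,yes|no
mat_h_epiduralbirth,mat,harmonised,binary,,Epidural recorded in birth analgesia,charlie,analgesia_text,identity,1=>yes|spinal=>no|remifentanil=>no|none recorded=>no,full,yes|no
mat_h_epidural,mat,harmonised,binary,,Epidural in labour or at birth (any source affirmative),all,mat_h_epidurallab;mat_h_epiduralbirth,merge_any,,,yes|no
mat_h_ebl,mat,harmonised,continuous,mL,Estimated blood loss,alpha,BloodLossMl,numeric,,,
mat_h_ebl,mat,harmonised,continuous,mL,Estimated blood loss,bravo,ebl_ml,numeric,,,
mat_h_ebl,mat,harmonised,continuous,mL,Estimated blood loss,charlie,blood_loss,numeric,,,
mat_h_sex,mat,harmonised,categorical,,Infant sex,alpha,InfantSex,identity,M=>male|F=>female,,male|female
mat_h_sex,mat,harmonised,categorical,,Infant sex,bravo,infant_sex,identity,Male=>male|Female=>female,,male|female
mat_h_sex,mat,harmonised,categorical,,Infant sex,charlie,sex_code,identity,1=>male|2=>female,,male|female
mat_h_bwt,mat,harmonised,continuous,g,Birthweight,alpha,BirthweightG,g_to_g,,,
mat_h_bwt,mat,harmonised,continuous,g,Birthweight,bravo,bwt_grams,g_to_g,,,
mat_h_bwt,mat,harmonised,continuous,g,Birthweight,charlie,birth_weight,g_to_g,,,
mat_c_bmi,mat,calculated,continuous,kg/m2,Body mass index from harmonised weight and height,all,mat_h_weight;mat_h_height,bmi,,,
neo_h_dob,neo,harmonised,date,date,Neonatal date of birth,all,neonatal_dob,date,,,
neo_h_sex,neo,harmonised,categorical,,Infant sex (neonatal record),all,neo_sex,identity,M=>male|F=>female,,male|female
neo_h_bwt,neo,harmonised,continuous,g,Birthweight (neonatal record),all,neo_bwt_g,g_to_g,,,
uss_h_scandate,uss,harmonised,date,date,Ultrasound scan date,all,event_date,date,,,
uss_h_fetalcount,uss,harmonised,continuous,count,Number of fetuses seen,all,fetal_count,numeric,,,
uss_h_sgaflag,uss,harmonised,binary,,Small-for-gestational-age suspected at scan,all,sga_suspected,identity,Y=>yes|N=>no,full,yes|no
act_h_eventdate,act,harmonised,date,date,Appointment or admission date,all,event_date,date,,,
act_h_eventtype,act,harmonised,categorical,,Activity type,all,event_type,identity,OP appointment=>outpatient|IP admission=>admission,,outpatient|admission
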